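test_that("metagene binning is exhaustive, exclusive and boundary-correct", {
  tx <- tx_from_seqs(random_rna(1000))
  sites <- tibble::tibble(gene_id = "t001", pos = c(0L, 900L, 999L, 500L))
  mg <- metagene(sites, tx)
  expect_equal(mg$sites$bin[mg$sites$pos == 0L], 1L)
  expect_equal(mg$sites$bin[mg$sites$pos == 900L], 10L)
  expect_equal(mg$sites$norm_pos[mg$sites$pos == 900L], 900)
  expect_equal(mg$sites$bin[mg$sites$pos == 999L], 10L)
  expect_equal(mg$sites$bin[mg$sites$pos == 500L], 6L)
  expect_equal(sum(mg$bin_counts$n), nrow(sites))
  expect_true(all(mg$sites$norm_pos >= 0 & mg$sites$norm_pos < 1000))

  expect_error(metagene(tibble::tibble(gene_id = "t001", pos = 1000L), tx),
               "beyond")
})

test_that("metagene filters subset sites before binning", {
  tx <- tx_from_seqs(c(random_rna(500), random_rna(500)),
                     eij = list(integer(0), c(250L)))
  sites <- tibble::tibble(
    gene_id = c("t001", "t002"), pos = c(100L, 400L),
    score = c(0.2, 0.9), context13 = c("NNNNNNACNNNNN", "NNNNNNAUNNNNN"))
  expect_equal(nrow(metagene(sites, tx, exclude_single_exon = TRUE)$sites), 1)
  expect_equal(nrow(metagene(sites, tx, min_score = 0.5)$sites), 1)
  expect_equal(nrow(metagene(sites, tx, motif_include = "AC")$sites), 1)
  expect_equal(nrow(metagene(sites, tx, motif_exclude = "AC")$sites), 1)
})

test_that("3'-biased placement concentrates sites in the last bin", {
  p <- sim_params(n_genes = 150, three_prime_bias = 2, seed = 12)
  tx <- simulate_transcriptome(p)
  st <- plant_m6a_sites(tx, p)
  st$pos <- st$position
  mg <- metagene(st, tx)
  counts <- mg$bin_counts$n
  expect_true(counts[10] == max(counts))
  expect_gt(counts[10], counts[1])
})

test_that("EIJ distance equals the brute-force minimum over junctions", {
  tx <- tx_from_seqs(c(random_rna(500), random_rna(300)),
                     eij = list(c(100L, 400L), integer(0)))
  sites <- tibble::tibble(gene_id = c("t001", "t002"), pos = c(150L, 50L))
  out <- eij_distance(sites, tx)
  expect_equal(out$eij_distance, c(50, NA))

  # property: random junction sets vs naive double loop
  withr::with_seed(13, {
    for (i in 1:25) {
      eij <- sort(sample(1:999, sample(1:8, 1)))
      pos <- sample(0:999, 20)
      got <- eij_distance(
        tibble::tibble(gene_id = "t001", pos = pos),
        tx_from_seqs(random_rna(1000), eij = list(eij)))$eij_distance
      want <- vapply(pos, function(p) min(abs(p - eij)), numeric(1))
      expect_equal(got, want)
    }
  })
})

test_that("nearest-secondary spacing picks the top site and its neighbour", {
  sites <- tibble::tibble(
    gene_id = c("g1", "g1", "g1", "g2"),
    pos = c(100L, 118L, 500L, 10L),
    score = c(0.9, 0.5, 0.4, 0.8))
  sp <- nearest_secondary_spacing(sites)
  expect_equal(nrow(sp$per_gene), 1)          # single-site gene excluded
  expect_equal(sp$per_gene$top_pos, 100L)
  expect_equal(sp$per_gene$distance, 18)
  expect_equal(sp$median_distance, 18)

  # invariant under row permutation
  sp2 <- nearest_secondary_spacing(sites[c(4, 3, 1, 2), ])
  expect_equal(sp2$per_gene, sp$per_gene)

  # score tie broken by 5'-most position
  tie <- tibble::tibble(gene_id = "g1", pos = c(10L, 30L, 90L),
                        score = c(0.7, 0.7, 0.1))
  expect_equal(nearest_secondary_spacing(tie)$per_gene$top_pos, 10L)
})

test_that("adjacent-site correlation behaves at the extremes", {
  # identical paired scores: r = 1
  sites <- tibble::tibble(
    gene_id = rep(sprintf("g%d", 1:10), each = 2),
    pos = rep(c(10L, 30L), 10),
    score = rep(seq(0.1, 0.9, length.out = 10), each = 2))
  res <- adjacent_score_correlation(sites, max_gap = 40)
  expect_equal(res$n_pairs, 10)
  expect_equal(res$r, 1)

  # fewer than 3 pairs: NA with warning
  expect_warning(res2 <- adjacent_score_correlation(sites[1:4, ], max_gap = 40),
                 "fewer")
  expect_true(is.na(res2$r))

  # pairs beyond the window are not collected
  far <- tibble::tibble(gene_id = "g1", pos = c(0L, 100L), score = c(0.5, 0.6))
  expect_equal(nrow(glorimap:::site_pairs(far, max_gap = 40)), 0)
})

test_that("shared per-gene effects induce positive adjacent correlation", {
  withr::with_seed(14, {
    gene_mu <- runif(120, 0.2, 0.8)
    sites <- tibble::tibble(
      gene_id = rep(sprintf("g%03d", 1:120), each = 2),
      pos = rep(c(10L, 35L), 120),
      score = pmin(1, pmax(0, rep(gene_mu, each = 2) + rnorm(240, 0, 0.05))))
    res <- adjacent_score_correlation(sites, max_gap = 40)
    expect_gt(res$r, 0.5)
    expect_lt(res$p, 0.01)

    # independent scores: r near 0
    sites$score <- runif(240)
    res0 <- adjacent_score_correlation(sites, max_gap = 40)
    expect_lt(abs(res0$r), 3 / sqrt(118))
  })
})

test_that("3'-most bin score contrast detects a planted shift", {
  withr::with_seed(15, {
    tx <- tx_from_seqs(vapply(rep(1000, 40), random_rna, character(1)))
    sites <- tibble::tibble(
      gene_id = rep(tx$gene_id, each = 10),
      pos = as.integer(rep(seq(50, 950, by = 100), 40)))
    sites$score <- runif(nrow(sites), 0.3, 0.7)
    null_res <- score_by_bin(sites, tx)
    expect_gt(null_res$p, 0.001)

    last <- sites$pos >= 900
    sites$score[last] <- sites$score[last] + 0.2
    shift_res <- score_by_bin(sites, tx)
    expect_lt(shift_res$p, 0.01)
    expect_gt(shift_res$mean_diff, 0.1)
  })

  # degenerate input: single site
  one <- tibble::tibble(gene_id = "t001", pos = 10L, score = 0.5)
  tx1 <- tx_from_seqs(random_rna(100))
  expect_true(is.na(score_by_bin(one, tx1)$p))
})
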