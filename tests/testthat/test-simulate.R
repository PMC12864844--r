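test_that("transcriptome honours GC content, exon structure and determinism", {
  p <- sim_params(n_genes = 100, length_range = c(1000L, 2000L), seed = 1)
  tx <- simulate_transcriptome(p)
  expect_equal(nrow(tx), 100)
  expect_equal(tx$length, nchar(tx$sequence))

  gc <- vapply(tx$sequence, function(s) {
    v <- strsplit(s, "")[[1]]
    mean(v %in% c("C", "G"))
  }, numeric(1), USE.NAMES = FALSE)
  expect_gte(mean(gc), 0.29)
  expect_lte(mean(gc), 0.35)

  # junctions strictly inside (0, length)
  ok <- purrr::map2_lgl(tx$eij_positions, tx$length,
                        ~ all(.x > 0 & .x < .y) && !is.unsorted(.x))
  expect_true(all(ok))

  # single-exon setting yields no junctions
  p1 <- sim_params(n_genes = 20, exon_count_range = c(1L, 1L), seed = 2)
  tx1 <- simulate_transcriptome(p1)
  expect_true(all(lengths(tx1$eij_positions) == 0))

  # same seed reproduces identical FASTA bytes
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_transcript_fasta(simulate_transcriptome(p), f1)
  write_transcript_fasta(simulate_transcriptome(p), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted sites follow the +1/+4 sequence rules and EIJ exclusion", {
  p <- sim_params(n_genes = 80, seed = 3)
  tx <- simulate_transcriptome(p)
  sites <- plant_m6a_sites(tx, p)
  expect_gt(nrow(sites), 50)

  idx <- match(sites$gene_id, tx$gene_id)
  base_at <- function(off) {
    substr(tx$sequence[idx], sites$position + 1L + off, sites$position + 1L + off)
  }
  expect_true(all(base_at(0L) == "A"))
  plus1 <- base_at(1L)
  expect_true(all(plus1 %in% c("C", "U")))
  expect_true(all(base_at(4L)[plus1 == "U"] == "U"))
  # never within the exclusion zone of a junction
  expect_true(all(is.na(sites$eij_distance) |
                    sites$eij_distance >= p$eij_exclusion_nt))

  # stoichiometry of +1C sites concentrates at the Beta(20, 2) mean
  s_high <- sites$stoichiometry[sites$rule_class == "plus1C"]
  beta_mean <- 20 / 22
  beta_se <- sqrt(20 * 2 / ((22)^2 * 23)) / sqrt(length(s_high))
  expect_lt(abs(mean(s_high) - beta_mean), 3 * beta_se)

  # a transcript without eligible adenosines yields no sites
  tx0 <- tx_from_seqs(c("GGGGGGGGGG", "CCCCCCCCCC"))
  tx0$expression_weight <- 1
  expect_equal(nrow(plant_m6a_sites(tx0, p)), 0)
})

test_that("read conversion bookkeeping: only A-to-G changes, counts conserved", {
  p <- sim_params(n_genes = 10, length_range = c(300L, 500L),
                  depth_mean = 50, seed = 4)
  tx <- simulate_transcriptome(p)
  sites <- plant_m6a_sites(tx, p)
  reads <- simulate_glori_reads(tx, sites, p)
  ref <- setNames(tx$sequence, tx$gene_id)

  chk <- reads |>
    dplyr::slice_sample(n = 300) |>
    purrr::pmap_lgl(function(gene_id, start, seq, treated, ...) {
      refseq <- substr(ref[[gene_id]], start + 1L, start + nchar(seq))
      rv <- strsplit(refseq, "")[[1]]
      sv <- strsplit(seq, "")[[1]]
      diff <- which(rv != sv)
      if (!treated) return(length(diff) == 0)
      all(rv[diff] == "A" & sv[diff] == "G") &&
        sum(sv[rv == "A"] %in% c("A", "G")) == sum(rv == "A")
    })
  expect_true(all(chk))
})

test_that("site scores track stoichiometry and efficiency analytically", {
  tx <- tx_from_seqs(c(strrep("ACGUC", 30)))
  p <- flat_coverage_params(1, 150, depth = 500, efficiency = 1, seed = 5)
  # full methylation: site always A; all other As fully converted
  one_sample <- tibble::tibble(sample_id = "s1", condition = "control",
                               treated = TRUE, stoich_scale = 1)
  s1 <- tibble::tibble(gene_id = "t001", position = 50L, stoichiometry = 1)
  rd <- simulate_glori_reads(tx, s1, p, samples = one_sample)
  tr <- dplyr::filter(rd, treated)
  cts <- pileup_counts(tr, tx, min_reads_per_transcript = 1)
  expect_equal(glori_score(cts, "t001", 50L), 1)
  other_a <- dplyr::filter(glori_score(cts), pos != 50L)
  expect_true(all(other_a$score == 0))

  # zero methylation at efficiency e: expected score 1 - e
  p2 <- flat_coverage_params(1, 150, depth = 2000, efficiency = 0.95, seed = 6)
  s0 <- tibble::tibble(gene_id = "t001", position = 50L, stoichiometry = 0)
  rd0 <- simulate_glori_reads(tx, s0, p2, samples = one_sample)
  cts0 <- pileup_counts(rd0, tx, min_reads_per_transcript = 1)
  sc0 <- glori_score(cts0, "t001", 50L)
  n0 <- dplyr::filter(cts0, pos == 50L)
  se0 <- sqrt(0.05 * 0.95 / (n0$n_A + n0$n_G))
  expect_lt(abs(sc0 - 0.05), 3 * se0)

  # intermediate stoichiometry recovered within binomial error
  p3 <- flat_coverage_params(1, 150, depth = 500, efficiency = 1, seed = 7)
  s6 <- tibble::tibble(gene_id = "t001", position = 50L, stoichiometry = 0.6)
  rd6 <- simulate_glori_reads(tx, s6, p3, samples = one_sample)
  cts6 <- pileup_counts(rd6, tx, min_reads_per_transcript = 1)
  sc6 <- glori_score(cts6, "t001", 50L)
  n6 <- dplyr::filter(cts6, pos == 50L)
  expect_lt(abs(sc6 - 0.6), 3 * sqrt(0.6 * 0.4 / (n6$n_A + n6$n_G)))

  # planting a site on a non-A base is rejected
  bad <- tibble::tibble(gene_id = "t001", position = 1L, stoichiometry = 0.5)
  expect_error(simulate_glori_reads(tx, bad, p), "not an adenosine")
})

test_that("homolog simulation realises class-specific substitution rates", {
  set.seed(8)
  tx <- tx_from_seqs(vapply(rep(2000, 25), random_rna, character(1)))

  # zero rates: identical sequences
  h0 <- simulate_homologs(tx, 0, 0, seed = 1)
  expect_identical(h0$sequence, tx$sequence)

  # realized class rates match within 3 binomial s.e.
  h <- simulate_homologs(tx, 0.05, 0.15, seed = 2)
  refv <- strsplit(paste(tx$sequence, collapse = ""), "")[[1]]
  homv <- strsplit(paste(h$sequence, collapse = ""), "")[[1]]
  is_cg <- refv %in% c("C", "G")
  r_cg <- mean(refv[is_cg] != homv[is_cg])
  r_at <- mean(refv[!is_cg] != homv[!is_cg])
  expect_lt(abs(r_cg - 0.15), 3 * sqrt(0.15 * 0.85 / sum(is_cg)))
  expect_lt(abs(r_at - 0.05), 3 * sqrt(0.05 * 0.95 / sum(!is_cg)))

  # determinism
  expect_identical(simulate_homologs(tx, 0.05, 0.15, seed = 2)$sequence,
                   h$sequence)
  expect_error(simulate_homologs(tx, 1.2, 0.1), "rates")
})

test_that("DE table plants the conditional effect and the expression confound", {
  cond_diff <- function(de) {
    de$bin <- dplyr::ntile(log10(de$baseMean), 10)
    per_bin <- de |>
      dplyr::group_by(bin) |>
      dplyr::summarise(
        d = mean(de_true[has_m6a]) - mean(de_true[!has_m6a]),
        w = dplyr::n(), .groups = "drop")
    sum(per_bin$d * per_bin$w, na.rm = TRUE) / sum(per_bin$w[!is.na(per_bin$d)])
  }
  de0 <- simulate_de_table(20000, effect = 0, seed = 1)
  expect_lt(abs(cond_diff(de0)), 0.02)
  de2 <- simulate_de_table(20000, effect = 0.2, seed = 2)
  expect_lt(abs(cond_diff(de2) - 0.2), 0.03)

  # m6A label is expression-confounded (detectability)
  expect_gt(mean(log10(de2$baseMean[de2$has_m6a])),
            mean(log10(de2$baseMean[!de2$has_m6a])))
  # determinism
  expect_identical(simulate_de_table(500, effect = 0.1, seed = 9),
                   simulate_de_table(500, effect = 0.1, seed = 9))
})

test_that("coexpression sets have the exact requested overlap", {
  s <- simulate_coexpression_sets(200, c(10, 20), 5, seed = 1)
  expect_length(s$set_a, 10)
  expect_length(s$set_b, 20)
  expect_length(intersect(s$set_a, s$set_b), 5)
  expect_equal(jaccard(s$set_a, s$set_b), 0.2)

  full <- simulate_coexpression_sets(50, c(10, 10), 10, seed = 2)
  expect_equal(jaccard(full$set_a, full$set_b), 1)
  disj <- simulate_coexpression_sets(50, c(10, 10), 0, seed = 3)
  expect_equal(jaccard(disj$set_a, disj$set_b), 0)
  expect_error(simulate_coexpression_sets(50, c(10, 10), 11), "overlap")
  expect_error(simulate_coexpression_sets(15, c(10, 10), 2), "fit")
})
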