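test_that("pileup tallies bases exactly and applies read/transcript filters", {
  tx <- tx_from_seqs("ACGUA")
  rd <- tibble::tibble(gene_id = "t001", start = 0L,
                       seq = rep("ACG", 3), sample_id = "s1")
  cts <- pileup_counts(rd, tx, min_reads_per_transcript = 1)
  expect_equal(cts$n_A, c(3L, 0L, 0L))
  expect_equal(cts$n_C, c(0L, 3L, 0L))
  expect_equal(cts$n_G, c(0L, 0L, 3L))
  expect_equal(cts$ref, c("A", "C", "G"))
  expect_equal(cts$coverage, c(3L, 3L, 3L))

  # a transcript with 9 reads is dropped under the 10-read floor
  rd9 <- tibble::tibble(gene_id = "t001", start = 0L,
                        seq = rep("ACG", 9), sample_id = "s1")
  expect_equal(nrow(pileup_counts(rd9, tx)), 0)
  rd10 <- dplyr::bind_rows(rd9, rd9[1, ])
  expect_gt(nrow(pileup_counts(rd10, tx)), 0)

  # empty input: empty output, no error
  expect_equal(nrow(pileup_counts(rd[0, ], tx)), 0)

  # reads beyond the transcript end are skipped with a warning
  rd_oob <- tibble::tibble(gene_id = "t001", start = c(0L, 4L),
                           seq = c("ACG", "ACG"), sample_id = "s1")
  expect_warning(out <- pileup_counts(rd_oob, tx, min_reads_per_transcript = 1),
                 "outside")
  expect_equal(sum(out$coverage), 3L)

  # over-long read spans are removed
  long_tx <- tx_from_seqs(random_rna(800))
  rd_long <- tibble::tibble(gene_id = "t001", start = 0L,
                            seq = substr(long_tx$sequence, 1, 750),
                            sample_id = "s1")
  expect_equal(nrow(pileup_counts(rd_long, long_tx,
                                  min_reads_per_transcript = 1)), 0)
})

test_that("GLORI score is A/(A+G) with the A+G >= 10 filter", {
  cts <- tibble::tibble(
    sample_id = "s1", gene_id = "t001", pos = c(0L, 1L, 2L, 3L),
    ref = c("A", "A", "A", "C"),
    n_A = c(9L, 0L, 5L, 2L), n_C = 0L, n_G = c(1L, 20L, 4L, 1L), n_U = 0L,
    coverage = c(10L, 20L, 9L, 3L))
  expect_equal(glori_score(cts, "t001", 0L), 0.9)
  expect_equal(glori_score(cts, "t001", 1L), 0)
  expect_true(is.na(glori_score(cts, "t001", 2L)))     # A+G = 9 < 10
  expect_error(glori_score(cts, "t001", 3L), "not A")

  tab <- glori_score(cts)
  expect_equal(nrow(tab), 3)                            # only reference As
  expect_equal(tab$ag_coverage, c(10L, 20L, 9L))
})

test_that("background is the pooled unconverted-adenine fraction per sample", {
  cts <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 2),
    gene_id = "t001", pos = rep(c(0L, 1L), 2),
    ref = "A",
    n_A = c(0L, 0L, 10L, 30L), n_C = 0L,
    n_G = c(50L, 30L, 0L, 0L), n_U = 0L,
    coverage = c(50L, 30L, 10L, 30L))
  bg <- estimate_background(cts)
  expect_equal(bg$background[bg$sample_id == "s1"], 0)   # fully converted
  expect_equal(bg$background[bg$sample_id == "s2"], 1)   # fully protected
  expect_error(estimate_background(cts[0, ]), "empty")
})

test_that("vectorised Fisher tail equals fisher.test on small tables", {
  grid <- expand.grid(a = c(0L, 2L, 5L, 50L), g = c(1L, 10L, 50L),
                      bgA = c(5L, 100L), bgG = c(200L, 5000L))
  p_fast <- glorimap:::fisher_p_greater(grid$a, grid$g, grid$bgA, grid$bgG)
  p_ref <- mapply(function(a, g, bgA, bgG) {
    stats::fisher.test(matrix(c(a, g, bgA, bgG), 2, byrow = TRUE),
                       alternative = "greater")$p.value
  }, grid$a, grid$g, grid$bgA, grid$bgG)
  expect_equal(p_fast, unname(p_ref), tolerance = 1e-12)
})

test_that("call_sites applies the score, coverage and Fisher filters", {
  mk_cts <- function(nA, nG) tibble::tibble(
    sample_id = "s1", gene_id = "t001", pos = 0L, ref = "A",
    n_A = nA, n_C = 0L, n_G = nG, n_U = 0L, coverage = nA + nG)
  bg <- tibble::tibble(sample_id = "s1", bg_A = 10L, bg_G = 990L,
                       background = 0.01)

  # strong site: score 0.5, p tiny
  calls <- call_sites(mk_cts(50L, 50L), background = bg)
  expect_equal(nrow(calls), 1)
  expect_lt(calls$fisher_p, 1e-10)

  # score 2/30 = 0.067 <= 0.1: filtered despite Fisher significance
  expect_equal(nrow(call_sites(mk_cts(2L, 28L), background = bg)), 0)

  # missing background errors
  bg2 <- dplyr::mutate(bg, sample_id = "other")
  expect_error(call_sites(mk_cts(50L, 50L), background = bg2), "background")
})

test_that("raising thresholds never increases the number of called sites", {
  p <- sim_params(n_genes = 30, depth_mean = 150, seed = 11)
  tx <- simulate_transcriptome(p)
  st <- plant_m6a_sites(tx, p)
  rd <- simulate_glori_reads(tx, st, p)
  cts <- pileup_counts(dplyr::filter(rd, treated), tx)
  n_calls <- function(ms, mc) nrow(call_sites(cts, min_score = ms,
                                              min_count = mc))
  expect_gte(n_calls(0.1, 10), n_calls(0.3, 10))
  expect_gte(n_calls(0.3, 10), n_calls(0.5, 10))
  expect_gte(n_calls(0.1, 10), n_calls(0.1, 20))
  expect_gte(n_calls(0.1, 20), n_calls(0.1, 40))

  # per-sample AG coverage equals the pileup A+G at every emitted site
  calls <- call_sites(cts)
  ps <- attr(calls, "per_sample")
  ref <- dplyr::semi_join(glori_score(cts), calls, by = c("gene_id", "pos"))
  expect_equal(dplyr::arrange(ps[, c("gene_id", "pos", "sample_id",
                                     "ag_coverage")],
                              gene_id, pos, sample_id),
               dplyr::arrange(ref[, c("gene_id", "pos", "sample_id",
                                      "ag_coverage")],
                              gene_id, pos, sample_id))
})

test_that("condition aggregation takes medians over replicates", {
  long <- tibble::tibble(
    gene_id = "t001", pos = 0L,
    sample_id = c("c1", "c2", "c3", "k1"),
    score = c(0.8, 0.9, 1.0, 0.2))
  cmap <- c(c1 = "control", c2 = "control", c3 = "control", k1 = "kd")
  agg <- aggregate_conditions(long, cmap)
  med <- agg$medians
  expect_equal(med$median_score[med$condition == "control"], 0.9)
  expect_equal(med$median_score[med$condition == "kd"], 0.2)  # single rep
  sm <- agg$summary
  expect_equal(sm$n_sites[sm$condition == "control" & sm$cutoff == 0.5], 1L)
  expect_equal(sm$n_sites[sm$condition == "kd" & sm$cutoff == 0.5], 0L)
})
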