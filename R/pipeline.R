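#' Pipeline configuration
#'
#' A validated list of every stage threshold and seed used by
#' [run_pipeline()]. Unknown keys are rejected so typos cannot silently fall
#' back to defaults; the resolved configuration is written alongside every
#' pipeline run.
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `glori_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    sim = sim_params(),
    min_reads_per_transcript = 10,
    max_read_span = 700,
    min_count = 10,
    min_score = 0.1,
    alpha = 0.05,
    replicate_support = 1,
    max_gap = 40,
    score_lo = 0.4,
    score_hi = 0.7,
    min_spanning = 10,
    model_min_cov = 40,
    model_test_frac = 0.2,
    model_seed = 7L,
    top_frac = 0.01,
    coherent_cut = 0.8,
    low_cut = 0.1,
    max_hamming = 3,
    min_basemean = 200,
    n_bins = 10,
    boot_frac = 0.8,
    boot_iter = 1000,
    perm_iter = 10000,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(over)] <- over
  structure(defaults, class = "glori_config")
}

#' Run the synthetic end-to-end pipeline
#'
#' Simulates a transcriptome, methylation truth and GLORI libraries, then
#' runs every analysis stage in dependency order — scoring/site calling,
#' topology, single-molecule linkage, the sequence-context model,
#' cross-species conservation and the enrichment statistics — writing each
#' stage's table plus a resolved-config snapshot and a log to `outdir`.
#' Rerunning with the same configuration reproduces the outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @return invisibly, a named list of the stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "glori_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "pipeline.log")
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                                "\n", file = logf, append = TRUE)
  cfg_out <- unclass(config)
  cfg_out$sim <- unclass(cfg_out$sim)
  jsonlite::write_json(cfg_out, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  log_line("simulate")
  tx <- simulate_transcriptome(config$sim)
  sites_true <- plant_m6a_sites(tx, config$sim)
  reads <- simulate_glori_reads(tx, sites_true, config$sim)
  write_transcript_fasta(tx, file.path(outdir, "transcripts.fasta"))
  write_eij_bed(tx, file.path(outdir, "exons.bed"))
  write_site_table(sites_true, file.path(outdir, "true_sites.tsv"))

  log_line("score")
  treated <- dplyr::filter(reads, .data$treated)
  counts <- pileup_counts(treated, tx,
                          min_reads_per_transcript = config$min_reads_per_transcript,
                          max_read_span = config$max_read_span)
  cond_map <- setNames(reads$condition[!duplicated(reads$sample_id)],
                       reads$sample_id[!duplicated(reads$sample_id)])
  calls <- call_sites(counts, transcripts = tx, condition_map = cond_map,
                      min_score = config$min_score,
                      min_count = config$min_count, alpha = config$alpha,
                      replicate_support = config$replicate_support)
  write_site_table(calls, file.path(outdir, "site_calls.tsv"))

  med_col <- grep("^median_", names(calls), value = TRUE)[1]
  calls$score <- calls[[med_col]]

  log_line("topology")
  mg <- metagene(calls, tx)
  calls_eij <- eij_distance(calls, tx)
  spacing <- nearest_secondary_spacing(calls)
  corr <- tryCatch(adjacent_score_correlation(calls, config$max_gap),
                   warning = function(w) list(r = NA, p = NA, n_pairs = 0))
  readr::write_tsv(mg$bin_counts, file.path(outdir, "metagene_bins.tsv"))
  readr::write_tsv(calls_eij, file.path(outdir, "sites_eij.tsv"))

  log_line("linkage")
  pairs <- select_pairs(calls, config$max_gap, config$score_lo,
                        config$score_hi, score_col = "score")
  linkage <- NULL
  if (nrow(pairs)) {
    ctrl_reads <- dplyr::filter(reads, .data$treated)
    linkage <- joint_read_table(ctrl_reads, pairs) |>
      linkage_chi_square(min_spanning = config$min_spanning)
    readr::write_tsv(linkage, file.path(outdir, "linkage_pairs.tsv"))
  }

  log_line("motif model")
  model <- NULL
  cov_ps <- attr(calls, "per_sample")
  cov_by_site <- cov_ps |>
    dplyr::group_by(.data$gene_id, .data$pos) |>
    dplyr::summarise(coverage = median(.data$ag_coverage), .groups = "drop")
  md <- dplyr::left_join(calls_eij, cov_by_site, by = c("gene_id", "pos"))
  if (nrow(md) >= 200) {
    cm <- context_matrix(md, score_col = "score", cov_col = "coverage")
    model <- tryCatch(
      fit_score_model(cm, min_cov = config$model_min_cov,
                      test_frac = config$model_test_frac,
                      seed = config$model_seed),
      error = function(e) NULL)
    if (!is.null(model)) {
      readr::write_tsv(model$predictions, file.path(outdir, "predictions.tsv"))
      jsonlite::write_json(glance(model), file.path(outdir, "model.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  log_line("conservation")
  hom <- simulate_homologs(tx, seed = config$seed + 10L)
  matches <- scan_homologs(calls, hom, max_hamming = config$max_hamming)
  cons <- tryCatch(positional_conservation(matches),
                   error = function(e) NULL)
  if (!is.null(cons))
    readr::write_tsv(cons, file.path(outdir, "conservation.tsv"))

  log_line("enrichment")
  de <- simulate_de_table(n_genes = 3000, effect = 0.1,
                          seed = config$seed + 20L)
  boot <- expression_matched_bootstrap(
    de, min_basemean = config$min_basemean, alpha = config$alpha,
    n_bins = config$n_bins, frac = config$boot_frac,
    n_iter = config$boot_iter, seed = config$seed)
  sets <- simulate_coexpression_sets(500, c(40, 40), 15,
                                     seed = config$seed + 30L)
  overlap <- jaccard_permutation(sets$set_a, sets$set_b, sets$universe,
                                 n_perm = config$perm_iter,
                                 seed = config$seed)
  jsonlite::write_json(list(
    bootstrap = list(observed_diff = boot$observed_diff, p = boot$p_value,
                     ci = boot$ci),
    overlap = list(jaccard = overlap$jaccard, p = overlap$p_value),
    spacing_median = spacing$median_distance,
    adjacent_score_r = corr$r
  ), file.path(outdir, "enrichment.json"), auto_unbox = TRUE, digits = NA)

  log_line("done")
  invisible(list(transcripts = tx, true_sites = sites_true, calls = calls,
                 metagene = mg, spacing = spacing, correlation = corr,
                 linkage = linkage, model = model, conservation = cons,
                 bootstrap = boot, overlap = overlap))
}
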