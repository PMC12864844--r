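#' Per-position nucleotide pileup from transcript-space reads
#'
#' Tallies A/C/G/U counts at every covered transcript position, per sample.
#' Reads longer than `max_read_span` are discarded (long mappings are
#' unreliable), transcripts seen by fewer than `min_reads_per_transcript`
#' reads in a sample are dropped entirely, and reads extending beyond their
#' transcript are skipped with a warning.
#'
#' @param reads tibble with `gene_id`, `start` (0-based), `seq`, `sample_id`.
#' @param transcripts tibble with `gene_id`, `sequence`, `length`.
#' @param min_reads_per_transcript minimum reads per transcript per sample.
#' @param max_read_span maximum allowed read span (nt).
#' @return tibble with `sample_id`, `gene_id`, `pos` (0-based), `ref`
#'   (reference base), `n_A`, `n_C`, `n_G`, `n_U` and `coverage`.
#' @examples
#' tx <- tibble::tibble(gene_id = "g1", sequence = "ACGU", length = 4L)
#' rd <- tibble::tibble(gene_id = "g1", start = 0L, seq = c("ACG", "ACG"),
#'                      sample_id = "s1")
#' pileup_counts(rd, tx, min_reads_per_transcript = 1)
#' @export
pileup_counts <- function(reads, transcripts, min_reads_per_transcript = 10,
                          max_read_span = 700) {
  empty <- tibble(sample_id = character(), gene_id = character(),
                  pos = integer(), ref = character(), n_A = integer(),
                  n_C = integer(), n_G = integer(), n_U = integer(),
                  coverage = integer())
  if (!nrow(reads)) return(empty)
  reads <- dplyr::mutate(reads, .len = nchar(.data$seq))
  reads <- dplyr::filter(reads, .data$.len <= max_read_span)
  tx_len <- setNames(transcripts$length, transcripts$gene_id)
  oob <- reads$start < 0 | reads$start + reads$.len > tx_len[reads$gene_id] |
    is.na(tx_len[reads$gene_id])
  if (any(oob)) {
    warning(sum(oob), " read(s) outside transcript bounds skipped",
            call. = FALSE)
    reads <- reads[!oob, ]
  }
  reads <- dplyr::group_by(reads, .data$sample_id, .data$gene_id)
  reads <- dplyr::filter(reads, dplyr::n() >= min_reads_per_transcript)
  reads <- dplyr::ungroup(reads)
  if (!nrow(reads)) return(empty)

  ref_split <- setNames(transcripts$sequence, transcripts$gene_id)
  out <- reads |>
    dplyr::group_by(.data$sample_id, .data$gene_id) |>
    dplyr::group_map(function(df, key) {
      lens <- nchar(df$seq)
      posl <- rep(df$start, lens) + sequence(lens) - 1L
      base <- utf8ToInt(paste(df$seq, collapse = ""))
      tab <- table(factor(posl, levels = sort(unique(posl))),
                   factor(base, levels = c(.CODE_A, .CODE_C, .CODE_G, .CODE_U)))
      pos <- as.integer(rownames(tab))
      tibble(sample_id = key$sample_id, gene_id = key$gene_id, pos = pos,
             ref = substring(ref_split[[key$gene_id]], pos + 1L, pos + 1L),
             n_A = as.integer(tab[, 1]), n_C = as.integer(tab[, 2]),
             n_G = as.integer(tab[, 3]), n_U = as.integer(tab[, 4]))
    }, .keep = TRUE) |>
    dplyr::bind_rows()
  dplyr::mutate(out, coverage = .data$n_A + .data$n_C + .data$n_G + .data$n_U)
}

#' GLORI score: fraction of A among A+G reads at reference adenosines
#'
#' The score `A / (A + G)` estimates methylation stoichiometry: methylated
#' adenosines are protected from deamination and sequence as A, unmethylated
#' ones as G. Positions with fewer than `min_count` combined A+G reads are
#' filtered (score `NA`).
#'
#' With `gene_id` and `position` supplied, returns the single score (erroring
#' if the reference base is not A); otherwise returns the full per-sample
#' table of reference-A positions.
#'
#' @param counts output of [pileup_counts()].
#' @param gene_id,position optional single position to score.
#' @param min_count minimum combined A+G count.
#' @return a tibble with `score` and `ag_coverage` columns, or a single
#'   numeric score.
#' @export
glori_score <- function(counts, gene_id = NULL, position = NULL,
                        min_count = 10) {
  if (!is.null(gene_id)) {
    row <- dplyr::filter(counts, .data$gene_id == .env$gene_id,
                         .data$pos == .env$position)
    if (!nrow(row)) return(NA_real_)
    if (any(row$ref != "A"))
      stop("reference base at requested position is not A", call. = FALSE)
    ag <- row$n_A + row$n_G
    return(ifelse(ag < min_count, NA_real_, row$n_A / ag)[1])
  }
  counts |>
    dplyr::filter(.data$ref == "A") |>
    dplyr::mutate(ag_coverage = .data$n_A + .data$n_G,
                  score = ifelse(.data$ag_coverage < min_count,
                                 NA_real_, .data$n_A / .data$ag_coverage))
}

#' Per-sample background adenine frequency
#'
#' Pooled `sum(A) / sum(A + G)` over all reference-A positions of each
#' sample: the overall unconverted-adenine fraction, used as the null rate of
#' the site-calling Fisher test. Pooling counts (rather than averaging
#' per-position ratios) keeps the estimator stable at low coverage.
#'
#' @param counts output of [pileup_counts()].
#' @return tibble `sample_id`, `bg_A`, `bg_G`, `background`.
#' @export
estimate_background <- function(counts) {
  if (!nrow(counts)) stop("empty counts", call. = FALSE)
  out <- counts |>
    dplyr::filter(.data$ref == "A") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(bg_A = sum(.data$n_A), bg_G = sum(.data$n_G),
                     .groups = "drop")
  if (any(out$bg_A + out$bg_G == 0))
    stop("zero A+G total in a sample; cannot estimate background",
         call. = FALSE)
  dplyr::mutate(out, background = .data$bg_A / (.data$bg_A + .data$bg_G))
}

# One-sided Fisher exact p (A-enrichment of (a, g) over background (bgA, bgG)).
# Identical to fisher.test(matrix(c(a, g, bgA, bgG), 2), alternative =
# "greater")$p.value, vectorised via the hypergeometric tail.
fisher_p_greater <- function(a, g, bgA, bgG) {
  phyper(a - 1, a + bgA, g + bgG, a + g, lower.tail = FALSE)
}

#' Call m6A sites from per-sample pileups
#'
#' For every reference-A position in every sample a one-sided Fisher exact
#' test compares its (A, G) counts with the sample's pooled background; the
#' position passes in that sample when score > `min_score`, A+G >=
#' `min_count` and p < `alpha` (optionally Benjamini-Hochberg adjusted). A
#' site is emitted when it passes in at least `replicate_support` samples.
#'
#' @param counts output of [pileup_counts()].
#' @param background output of [estimate_background()]; computed if `NULL`.
#' @param transcripts optional; when given, each site carries its 13-nt
#'   sequence context.
#' @param condition_map optional named character mapping `sample_id` to
#'   condition; adds per-condition median score columns
#'   (`median_<condition>`).
#' @param min_score score threshold (exclusive).
#' @param min_count minimum combined A+G count.
#' @param alpha significance threshold for the Fisher test.
#' @param replicate_support number of samples a site must pass in.
#' @param bh apply Benjamini-Hochberg adjustment per sample before `alpha`.
#' @return tibble of site calls, one row per site, with `gene_id`, `pos`,
#'   `replicate_support`, `fisher_p` (minimum across samples), optional
#'   `context13` and condition medians; per-sample scores/coverages are in
#'   the long tibble attached as attribute `"per_sample"`.
#' @export
call_sites <- function(counts, background = NULL, transcripts = NULL,
                       condition_map = NULL, min_score = 0.1, min_count = 10,
                       alpha = 0.05, replicate_support = 1, bh = FALSE) {
  if (is.null(background)) background <- estimate_background(counts)
  scored <- glori_score(counts, min_count = min_count)
  miss <- setdiff(unique(scored$sample_id), background$sample_id)
  if (length(miss))
    stop("background missing for sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  scored <- dplyr::left_join(scored, background, by = "sample_id")
  scored <- dplyr::mutate(scored,
    fisher_p = fisher_p_greater(.data$n_A, .data$n_G, .data$bg_A, .data$bg_G))
  if (bh) {
    scored <- scored |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(fisher_p = p.adjust(.data$fisher_p, "BH")) |>
      dplyr::ungroup()
  }
  scored <- dplyr::mutate(scored,
    pass = !is.na(.data$score) & .data$score > min_score &
      .data$ag_coverage >= min_count & .data$fisher_p < alpha)

  calls <- scored |>
    dplyr::group_by(.data$gene_id, .data$pos) |>
    dplyr::summarise(replicate_support = sum(.data$pass),
                     fisher_p = min(.data$fisher_p[.data$pass], Inf),
                     .groups = "drop") |>
    dplyr::filter(.data$replicate_support >= .env$replicate_support)
  per_sample <- dplyr::semi_join(scored, calls, by = c("gene_id", "pos"))

  if (!is.null(condition_map)) {
    med <- per_sample |>
      dplyr::mutate(condition = condition_map[.data$sample_id]) |>
      dplyr::filter(!is.na(.data$condition)) |>
      dplyr::group_by(.data$gene_id, .data$pos, .data$condition) |>
      dplyr::summarise(median_score = median(.data$score, na.rm = TRUE),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "condition",
                         values_from = "median_score",
                         names_prefix = "median_")
    calls <- dplyr::left_join(calls, med, by = c("gene_id", "pos"))
  }
  if (!is.null(transcripts)) {
    calls$context13 <- context_at(transcripts, calls$gene_id, calls$pos)
  }
  attr(calls, "per_sample") <- per_sample
  calls
}

#' Aggregate site calls to condition level
#'
#' Computes per-site median scores over each condition's replicates and, per
#' condition, the number of sites whose median exceeds each cutoff.
#'
#' @param site_calls output of [call_sites()] (uses its `"per_sample"`
#'   attribute) or a long tibble with `gene_id`, `pos`, `sample_id`, `score`.
#' @param condition_map named character mapping `sample_id` to condition.
#' @param cutoffs score cutoffs for the summary counts.
#' @return list with `medians` (site x condition tibble) and `summary`
#'   (condition x cutoff counts).
#' @export
aggregate_conditions <- function(site_calls, condition_map,
                                 cutoffs = c(0.1, 0.5, 0.9)) {
  long <- attr(site_calls, "per_sample") %||% site_calls
  long <- dplyr::mutate(long, condition = condition_map[.data$sample_id])
  medians <- long |>
    dplyr::filter(!is.na(.data$condition)) |>
    dplyr::group_by(.data$gene_id, .data$pos, .data$condition) |>
    dplyr::summarise(median_score = median(.data$score, na.rm = TRUE),
                     n_replicates = dplyr::n(), .groups = "drop")
  summary <- purrr::map(cutoffs, function(ct) {
    medians |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(cutoff = ct,
                       n_sites = sum(.data$median_score > ct, na.rm = TRUE),
                       .groups = "drop")
  }) |> dplyr::bind_rows()
  list(medians = medians, summary = summary)
}

# 13-nt context (6 up, site, 6 down), N-padded at transcript ends.
context_at <- function(transcripts, gene_id, pos, flank = 6L) {
  idx <- match(gene_id, transcripts$gene_id)
  padded <- paste0(strrep("N", flank), transcripts$sequence[idx],
                   strrep("N", flank))
  substr(padded, pos + 1L, pos + 2L * flank + 1L)
}
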