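#' Select adjacent site pairs for the single-molecule linkage test
#'
#' A pair qualifies when (1) the two sites lie within `max_gap` nt of each
#' other in the same gene, (2) both have a condition-median score inside
#' `[score_lo, score_hi]`, and (3) one of them is the gene's dominant site.
#' "Dominant" is implemented as the gene's highest-median-score site over all
#' sites supplied (ties broken 5'-most) — an interpretation, exposed here
#' rather than hard-coded deeper in the pipeline.
#'
#' @param sites tibble with `gene_id`, `pos` and a median-score column.
#' @param max_gap maximum separation (nt).
#' @param score_lo,score_hi inclusive score band for both sites.
#' @param score_col name of the median-score column.
#' @return tibble `gene_id`, `pos1`, `pos2` (pos1 < pos2), `gap`, `score1`,
#'   `score2`.
#' @export
select_pairs <- function(sites, max_gap = 40, score_lo = 0.4, score_hi = 0.7,
                         score_col = "median_control") {
  sites$.score <- sites[[score_col]]
  dominant <- sites |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(.data$.score), .data$pos, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", dom_pos = "pos")
  banded <- dplyr::filter(sites, .data$.score >= score_lo,
                          .data$.score <= score_hi)
  pairs <- site_pairs(banded, max_gap, ".score")
  if (!nrow(pairs)) {
    return(tibble(gene_id = character(), pos1 = integer(), pos2 = integer(),
                  gap = integer(), score1 = double(), score2 = double()))
  }
  pairs <- dplyr::left_join(pairs, dominant, by = "gene_id")
  pairs <- dplyr::filter(pairs, .data$pos1 == .data$dom_pos |
                           .data$pos2 == .data$dom_pos)
  dplyr::select(pairs, -"dom_pos")
}

#' Joint read-level base table for site pairs
#'
#' For each pair, reads spanning both positions are tallied by their base
#' combination: `n_AA`, `n_AG`, `n_GA`, `n_GG` (first letter = base at the
#' 5' site). Reads carrying any non-A/G base at either site are counted in
#' `n_other` and excluded from the 2x2 test (C/U at a reference adenosine is
#' uninterpretable under deamination chemistry).
#'
#' @param reads tibble with `gene_id`, `start`, `seq` (treated libraries).
#' @param pairs output of [select_pairs()].
#' @return `pairs` with count columns and `n_spanning`; pairs with no
#'   spanning reads are dropped with a warning.
#' @export
joint_read_table <- function(reads, pairs) {
  read_split <- split(reads[, c("start", "seq")], reads$gene_id)
  out <- purrr::pmap(pairs, function(gene_id, pos1, pos2, ...) {
    rd <- read_split[[gene_id]]
    row <- tibble(gene_id = gene_id, pos1 = pos1, pos2 = pos2, ...,
                  n_AA = 0L, n_AG = 0L, n_GA = 0L, n_GG = 0L, n_other = 0L,
                  n_spanning = 0L)
    if (is.null(rd)) return(row)
    span <- rd$start <= pos1 & rd$start + nchar(rd$seq) > pos2
    if (!any(span)) return(row)
    rd <- rd[span, ]
    b1 <- substr(rd$seq, pos1 - rd$start + 1L, pos1 - rd$start + 1L)
    b2 <- substr(rd$seq, pos2 - rd$start + 1L, pos2 - rd$start + 1L)
    ag <- b1 %in% c("A", "G") & b2 %in% c("A", "G")
    combo <- paste0(b1[ag], b2[ag])
    row$n_AA <- sum(combo == "AA")
    row$n_AG <- sum(combo == "AG")
    row$n_GA <- sum(combo == "GA")
    row$n_GG <- sum(combo == "GG")
    row$n_other <- sum(!ag)
    row$n_spanning <- nrow(rd)
    row
  }) |> dplyr::bind_rows()
  empty <- out$n_spanning == 0
  if (any(empty)) {
    warning(sum(empty), " pair(s) without spanning reads dropped",
            call. = FALSE)
    out <- out[!empty, ]
  }
  out
}

#' Chi-square test of methylation independence for site pairs
#'
#' A 2x2 chi-square test of independence (no continuity correction) on the
#' {A,G} x {A,G} joint counts of each pair. Pairs with fewer than
#' `min_spanning` informative reads, or with a zero margin, return `NA`.
#'
#' @param pair_counts output of [joint_read_table()].
#' @param min_spanning minimum informative (A/G-only) reads per pair.
#' @param correct apply the Yates continuity correction.
#' @return `pair_counts` with `chi2` and `p_value` columns.
#' @export
linkage_chi_square <- function(pair_counts, min_spanning = 10,
                               correct = FALSE) {
  res <- purrr::pmap(
    pair_counts[, c("n_AA", "n_AG", "n_GA", "n_GG")],
    function(n_AA, n_AG, n_GA, n_GG) {
      m <- matrix(c(n_AA, n_GA, n_AG, n_GG), 2L)
      if (sum(m) < min_spanning || any(rowSums(m) == 0) ||
          any(colSums(m) == 0)) {
        return(c(NA_real_, NA_real_))
      }
      ct <- suppressWarnings(chisq.test(m, correct = correct))
      c(unname(ct$statistic), ct$p.value)
    })
  pair_counts$chi2 <- vapply(res, `[`, numeric(1), 1)
  pair_counts$p_value <- vapply(res, `[`, numeric(1), 2)
  pair_counts
}

#' Survey the linkage p-value distribution
#'
#' Summarises a set of tested pairs: the p-value histogram, the fraction
#' significant at `alpha`, and a Kolmogorov-Smirnov uniformity statistic
#' (diagnostic: under site-wise independent methylation the p-values are
#' asymptotically uniform).
#'
#' @param pair_tests output of [linkage_chi_square()].
#' @param alpha significance level for the summary fraction.
#' @return object of class `glori_linkage_survey`: list with `p_values`,
#'   `n_tested`, `frac_significant`, `ks_statistic`, `ks_p`.
#' @export
linkage_survey <- function(pair_tests, alpha = 0.05) {
  p <- pair_tests$p_value[!is.na(pair_tests$p_value)]
  if (!length(p)) {
    return(structure(list(p_values = numeric(0), n_tested = 0L,
                          frac_significant = NA_real_,
                          ks_statistic = NA_real_, ks_p = NA_real_),
                     class = "glori_linkage_survey"))
  }
  ks <- suppressWarnings(ks.test(p, "punif"))
  structure(list(p_values = p, n_tested = length(p),
                 frac_significant = mean(p < alpha),
                 ks_statistic = unname(ks$statistic), ks_p = ks$p.value),
            class = "glori_linkage_survey")
}

#' @export
print.glori_linkage_survey <- function(x, ...) {
  cat("<glori_linkage_survey>", x$n_tested, "pairs tested;",
      sprintf("%.1f%% significant at 0.05; KS = %.3f\n",
              100 * x$frac_significant, x$ks_statistic))
  invisible(x)
}
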