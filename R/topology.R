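#' Metagene profile of site positions along length-normalised transcripts
#'
#' Scales each site position by `scale / length` and assigns it to one of
#' `bins` equal bins from 5' to 3' (position `p` of length `L` maps to bin
#' `floor(bins * p / L) + 1`, clamped to `bins`). Optional pre-filters mirror
#' common figure-level choices: score, replicate support, coverage, exon
#' count (single-exon exclusion) and context motif inclusion/exclusion
#' regular expressions.
#'
#' @param sites tibble with `gene_id`, `pos` and optionally `score`,
#'   `replicate_support`, `coverage`, `context13`.
#' @param transcripts tibble with `gene_id`, `length`, `eij_positions`.
#' @param bins number of bins.
#' @param scale normalised length scale.
#' @param min_score,min_support,min_cov optional filters.
#' @param exclude_single_exon drop sites on transcripts without junctions.
#' @param motif_include,motif_exclude optional regular expressions applied to
#'   `context13`.
#' @return object of class `glori_metagene`: list with `sites` (augmented
#'   tibble with `norm_pos`, `bin`), `bin_counts` and the binning parameters.
#' @export
metagene <- function(sites, transcripts, bins = 10, scale = 1000,
                     min_score = NULL, min_support = NULL, min_cov = NULL,
                     exclude_single_exon = FALSE, motif_include = NULL,
                     motif_exclude = NULL) {
  idx <- match(sites$gene_id, transcripts$gene_id)
  sites$length <- transcripts$length[idx]
  if (any(sites$pos >= sites$length | sites$pos < 0))
    stop("site position beyond transcript length", call. = FALSE)
  if (!is.null(min_score)) sites <- dplyr::filter(sites, .data$score >= min_score)
  if (!is.null(min_support))
    sites <- dplyr::filter(sites, .data$replicate_support >= min_support)
  if (!is.null(min_cov)) sites <- dplyr::filter(sites, .data$coverage >= min_cov)
  if (exclude_single_exon) {
    n_eij <- lengths(transcripts$eij_positions)[match(sites$gene_id,
                                                      transcripts$gene_id)]
    sites <- sites[n_eij > 0, ]
  }
  if (!is.null(motif_include))
    sites <- dplyr::filter(sites, stringr::str_detect(.data$context13,
                                                      motif_include))
  if (!is.null(motif_exclude))
    sites <- dplyr::filter(sites, !stringr::str_detect(.data$context13,
                                                       motif_exclude))
  sites <- dplyr::mutate(sites,
    norm_pos = floor(scale * .data$pos / .data$length),
    bin = pmin(floor(bins * .data$pos / .data$length) + 1L, bins))
  bin_counts <- sites |>
    dplyr::count(bin = factor(.data$bin, levels = seq_len(bins)),
                 .drop = FALSE) |>
    dplyr::mutate(bin = as.integer(as.character(.data$bin)))
  structure(list(sites = sites, bin_counts = bin_counts, bins = bins,
                 scale = scale),
            class = "glori_metagene")
}

#' @export
print.glori_metagene <- function(x, ...) {
  cat("<glori_metagene>", nrow(x$sites), "sites in", x$bins, "bins\n")
  print(x$bin_counts)
  invisible(x)
}

#' Distance of each site to its nearest exon-intron junction
#'
#' @param sites tibble with `gene_id`, `pos`.
#' @param transcripts tibble with `gene_id`, `eij_positions` (list column).
#' @return `sites` with an `eij_distance` column (`NA` for single-exon
#'   transcripts).
#' @export
eij_distance <- function(sites, transcripts) {
  eij <- transcripts$eij_positions[match(sites$gene_id, transcripts$gene_id)]
  sites$eij_distance <- purrr::map2_dbl(sites$pos, eij, function(p, e) {
    if (!length(e)) NA_real_ else min(abs(p - e))
  })
  sites
}

#' Distance from each gene's top site to its nearest secondary site
#'
#' For genes with at least two sites, the highest-scoring site is selected
#' (ties broken by the 5'-most position) and its distance to the nearest
#' other site recorded; the reported summary is the median over genes.
#'
#' @param sites tibble with `gene_id`, `pos` and a score column.
#' @param score_col name of the score column.
#' @return list with `per_gene` (gene, top site position/score, `distance`)
#'   and `median_distance`.
#' @export
nearest_secondary_spacing <- function(sites, score_col = "score") {
  per_gene <- sites |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::group_map(function(df, key) {
      sc <- df[[score_col]]
      top <- which(sc == max(sc))
      top <- top[which.min(df$pos[top])]
      tibble(gene_id = key$gene_id, top_pos = df$pos[top],
             top_score = sc[top],
             distance = min(abs(df$pos[-top] - df$pos[top])))
    }) |>
    dplyr::bind_rows()
  list(per_gene = per_gene,
       median_distance = if (nrow(per_gene)) median(per_gene$distance)
                         else NA_real_)
}

#' Correlation between scores of adjacent sites
#'
#' Collects all unordered within-gene site pairs separated by at most
#' `max_gap` nt and reports the Pearson correlation of their scores.
#'
#' @param sites tibble with `gene_id`, `pos` and a score column.
#' @param max_gap maximum pair separation (nt).
#' @param score_col name of the score column.
#' @return list with `r`, `p`, `n_pairs` and the `pairs` tibble; `r` is `NA`
#'   (with a warning) when fewer than 3 pairs qualify.
#' @export
adjacent_score_correlation <- function(sites, max_gap = 40,
                                       score_col = "score") {
  pairs <- site_pairs(sites, max_gap, score_col)
  if (nrow(pairs) < 3) {
    warning("fewer than 3 qualifying pairs; correlation undefined",
            call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, n_pairs = nrow(pairs),
                pairs = pairs))
  }
  ct <- cor.test(pairs$score1, pairs$score2, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = nrow(pairs),
       pairs = pairs)
}

# All unordered within-gene pairs with 1 <= gap <= max_gap.
site_pairs <- function(sites, max_gap, score_col = "score") {
  sites |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_map(function(df, key) {
      n <- nrow(df)
      if (n < 2) return(NULL)
      df <- df[order(df$pos), ]
      idx <- which(outer(df$pos, df$pos, function(a, b) b - a) >= 1 &
                     outer(df$pos, df$pos, function(a, b) b - a) <= max_gap,
                   arr.ind = TRUE)
      if (!nrow(idx)) return(NULL)
      tibble(gene_id = key$gene_id,
             pos1 = df$pos[idx[, 1]], pos2 = df$pos[idx[, 2]],
             gap = df$pos[idx[, 2]] - df$pos[idx[, 1]],
             score1 = df[[score_col]][idx[, 1]],
             score2 = df[[score_col]][idx[, 2]])
    }) |>
    dplyr::bind_rows()
}

#' Score distributions by metagene bin, with a 3'-most-bin contrast
#'
#' Bins sites as in [metagene()] and compares the scores in the 3'-most bin
#' against all other bins with a Student two-tailed t test.
#'
#' @param sites tibble with `gene_id`, `pos` and a score column.
#' @param transcripts tibble with `gene_id`, `length`.
#' @param bins number of bins.
#' @param score_col name of the score column.
#' @return list with `bin_scores` (tibble of bin, score), `mean_diff`
#'   (3'-most bin minus rest), `t_statistic`, `p`; statistics are `NA` when
#'   either group has fewer than 2 scores.
#' @export
score_by_bin <- function(sites, transcripts, bins = 10, score_col = "score") {
  mg <- metagene(sites, transcripts, bins = bins)
  df <- mg$sites
  df$score <- df[[score_col]]
  last <- df$score[df$bin == bins]
  rest <- df$score[df$bin != bins]
  if (length(last) < 2 || length(rest) < 2) {
    return(list(bin_scores = tibble(bin = df$bin, score = df$score),
                mean_diff = NA_real_, t_statistic = NA_real_, p = NA_real_))
  }
  tt <- t.test(last, rest, alternative = "two.sided")
  list(bin_scores = tibble(bin = df$bin, score = df$score),
       mean_diff = mean(last) - mean(rest),
       t_statistic = unname(tt$statistic), p = tt$p.value)
}
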