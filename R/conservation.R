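#' Best Hamming-window alignment of a site context in a homolog
#'
#' Slides the 13-nt motif across every window of the homolog sequence and
#' keeps the window with the most matching nucleotides. The match is flagged
#' `ambiguous` when two or more windows tie for the best score, and
#' `retained` only when unambiguous with Hamming distance at most
#' `max_hamming`. Sequences are U/T-normalised before scanning; matching is
#' indel-free by construction.
#'
#' @param motif context string (typically 13 nt).
#' @param sequence homolog sequence (RNA or DNA alphabet).
#' @param max_hamming retention threshold on the mismatch count.
#' @return one-row tibble: `best_offset` (0-based window start),
#'   `hamming_distance`, `match_vector` (list of logicals), `ambiguous`,
#'   `retained`; `NULL` when the homolog is shorter than the motif.
#' @export
best_hamming_alignment <- function(motif, sequence, max_hamming = 3) {
  k <- nchar(motif)
  m <- utf8ToInt(dna_to_rna(motif))
  s <- utf8ToInt(dna_to_rna(sequence))
  n <- length(s)
  if (n < k) return(NULL)
  nwin <- n - k + 1L
  mism <- integer(nwin)
  # shift-and-compare: one vectorised pass per motif position
  for (j in seq_len(k)) {
    mism <- mism + (s[j:(j + nwin - 1L)] != m[j])
  }
  best <- min(mism)
  hits <- which(mism == best)
  offset <- hits[1] - 1L
  ambiguous <- length(hits) >= 2L
  mv <- s[(offset + 1L):(offset + k)] == m
  tibble(best_offset = offset, hamming_distance = as.integer(best),
         match_vector = list(mv), ambiguous = ambiguous,
         retained = !ambiguous && best <= max_hamming)
}

#' Scan site contexts against homolog sequences
#'
#' Runs [best_hamming_alignment()] for every site against its gene's homolog
#' in each species; when a species offers several homolog sequences for a
#' gene, the best retained match is kept.
#'
#' @param sites tibble with `gene_id`, `pos`, `context13`.
#' @param homologs tibble with `gene_id`, `species`, `sequence` (e.g. from
#'   [simulate_homologs()]).
#' @param max_hamming retention threshold.
#' @return tibble of matches: site keys plus the alignment columns; sites
#'   whose homolog is shorter than the motif are skipped.
#' @export
scan_homologs <- function(sites, homologs, max_hamming = 3) {
  purrr::pmap(sites[, c("gene_id", "pos", "context13")],
              function(gene_id, pos, context13) {
    hs <- homologs[homologs$gene_id == gene_id, ]
    if (!nrow(hs)) return(NULL)
    per_species <- hs |>
      dplyr::group_by(.data$species) |>
      dplyr::group_map(function(df, key) {
        res <- purrr::map(df$sequence, best_hamming_alignment,
                          motif = context13, max_hamming = max_hamming)
        res <- dplyr::bind_rows(res)
        if (!nrow(res)) return(NULL)
        res <- res[order(!res$retained, res$hamming_distance), ][1, ]
        res$species <- key$species
        res
      }) |> dplyr::bind_rows()
    if (!nrow(per_species)) return(NULL)
    per_species$gene_id <- gene_id
    per_species$pos <- pos
    per_species$context13 <- context13
    per_species
  }) |> dplyr::bind_rows()
}

#' Positional conservation test across retained matches
#'
#' For each motif position, compares the proportion of conserved nucleotides
#' at that position against the pooled proportion over all other positions
#' (two-sample proportion test, Bonferroni-adjusted over the motif width).
#'
#' @param matches output of [scan_homologs()]; only `retained` rows are used.
#' @param min_matches minimum retained matches required.
#' @return tibble `offset`, `matches`, `total`, `prop`, `prop_other`, `p`,
#'   `p_adj`.
#' @export
positional_conservation <- function(matches, min_matches = 30) {
  matches <- matches[matches$retained, ]
  n <- nrow(matches)
  if (n < min_matches)
    stop("only ", n, " retained matches (need >= ", min_matches, ")",
         call. = FALSE)
  mv <- do.call(rbind, matches$match_vector)
  k <- ncol(mv)
  col_hits <- colSums(mv)
  total_hits <- sum(col_hits)
  res <- purrr::map(seq_len(k), function(j) {
    x <- c(col_hits[j], total_hits - col_hits[j])
    nn <- c(n, (k - 1L) * n)
    pt <- suppressWarnings(prop.test(x, nn))
    p <- pt$p.value
    # degenerate tables (both proportions 0 or 1) carry no evidence
    if (is.na(p) && x[1] / nn[1] == x[2] / nn[2]) p <- 1
    tibble(offset = j - 1L - (k - 1L) %/% 2L,
           matches = col_hits[j], total = n, prop = col_hits[j] / n,
           prop_other = x[2] / nn[2], p = p)
  }) |> dplyr::bind_rows()
  res$p_adj <- pmin(1, k * res$p)
  res
}

#' Substitution proportions split by reference base class
#'
#' At each motif position, compares the substitution fraction among matches
#' whose reference base is C or G against those with A or U (two-sample
#' proportion test per position, Bonferroni-adjusted). In low-GC genomes the
#' C/G class substitutes faster, which by itself depresses conservation at
#' C-rich positions such as +1.
#'
#' @param matches output of [scan_homologs()] (retained rows used); their
#'   `context13` supplies the reference bases.
#' @return tibble `offset`, `n_CG`, `sub_CG`, `n_AU`, `sub_AU`, `p`, `p_adj`
#'   (`NA` where a class is empty).
#' @export
substitution_by_class <- function(matches) {
  matches <- matches[matches$retained, ]
  if (!nrow(matches)) stop("no retained matches", call. = FALSE)
  mv <- do.call(rbind, matches$match_vector)
  k <- ncol(mv)
  refmat <- matrix(utf8ToInt(paste(matches$context13, collapse = "")),
                   ncol = k, byrow = TRUE)
  res <- purrr::map(seq_len(k), function(j) {
    is_cg <- refmat[, j] %in% c(.CODE_C, .CODE_G)
    sub <- !mv[, j]
    n_cg <- sum(is_cg); n_au <- sum(!is_cg)
    row <- tibble(offset = j - 1L - (k - 1L) %/% 2L,
                  n_CG = n_cg, sub_CG = NA_real_,
                  n_AU = n_au, sub_AU = NA_real_, p = NA_real_)
    if (n_cg > 0) row$sub_CG <- mean(sub[is_cg])
    if (n_au > 0) row$sub_AU <- mean(sub[!is_cg])
    if (n_cg > 0 && n_au > 0) {
      pt <- suppressWarnings(prop.test(c(sum(sub[is_cg]), sum(sub[!is_cg])),
                                       c(n_cg, n_au)))
      row$p <- pt$p.value
    }
    row
  }) |> dplyr::bind_rows()
  res$p_adj <- pmin(1, k * res$p)
  res
}
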