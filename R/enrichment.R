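#' Expression-matched stratified bootstrap for DE enrichment among m6A genes
#'
#' Tests whether m6A-marked genes are differentially expressed more (or
#' less) often than unmarked genes while controlling for the fact that m6A
#' detectability rises with expression. Genes with `baseMean >=
#' min_basemean` are kept, missing `padj` set to 1, and DE defined as
#' `padj < alpha`. The `log10(baseMean)` range is divided into `n_bins`
#' quantile bins; within each bin equal numbers of genes are sampled with
#' replacement from the m6A and non-m6A groups, the per-group totals equal
#' to `frac` times the smaller group. Per-bin quotas are proportional to the
#' pooled bin occupancy by default (`flat_bins = TRUE` uses a flat 1/n_bins
#' split). Each iteration records the DE-proportion difference (m6A minus
#' non-m6A); the empirical two-sided p doubles the smaller tail of the
#' bootstrap distribution around zero, and the 95% CI is its 2.5th-97.5th
#' percentile range.
#'
#' @param de_table tibble with `baseMean`, `padj` and `has_m6a` (logical).
#' @param min_basemean expression floor.
#' @param alpha DE definition threshold on `padj`.
#' @param n_bins number of quantile bins on `log10(baseMean)`.
#' @param frac per-group sampling total as a fraction of the smaller group.
#' @param n_iter bootstrap iterations.
#' @param seed integer seed.
#' @param flat_bins use equal quotas per bin instead of occupancy weights.
#' @return object of class `glori_bootstrap`: `observed_diff`, `boot_diffs`,
#'   `p_value`, `ci`, `matching_quality` (mean |difference in mean
#'   log10 baseMean| between the sampled groups), `quotas`, `n_per_group`.
#' @export
expression_matched_bootstrap <- function(de_table, min_basemean = 200,
                                         alpha = 0.05, n_bins = 10,
                                         frac = 0.8, n_iter = 1000,
                                         seed = 1L, flat_bins = FALSE) {
  df <- dplyr::filter(de_table, .data$baseMean >= min_basemean)
  df$padj[is.na(df$padj)] <- 1
  df$de <- df$padj < alpha
  df$logbm <- log10(df$baseMean)
  n1 <- sum(df$has_m6a); n0 <- sum(!df$has_m6a)
  if (n1 == 0 || n0 == 0)
    stop("both m6A groups must be non-empty after filtering", call. = FALSE)
  total <- round(frac * min(n1, n0))

  qs <- quantile(df$logbm, probs = seq(0, 1, length.out = n_bins + 1))
  qs[1] <- -Inf; qs[n_bins + 1] <- Inf
  df$bin <- cut(df$logbm, unique(qs), labels = FALSE, include.lowest = TRUE)
  nb <- max(df$bin)

  # indices per (bin, group)
  idx1 <- split(which(df$has_m6a), df$bin[df$has_m6a])
  idx0 <- split(which(!df$has_m6a), df$bin[!df$has_m6a])
  usable <- intersect(names(idx1), names(idx0))
  skipped <- setdiff(as.character(seq_len(nb)), usable)
  if (length(skipped))
    warning("bin(s) ", paste(skipped, collapse = ", "),
            " empty in one group; quota redistributed", call. = FALSE)
  occ <- vapply(usable, function(b) length(idx1[[b]]) + length(idx0[[b]]),
                numeric(1))
  w <- if (flat_bins) rep(1 / length(usable), length(usable)) else occ / sum(occ)
  quotas <- largest_remainder(total * w)
  names(quotas) <- usable

  de1 <- df$de; lb <- df$logbm
  withr::with_seed(as.integer(seed), {
    de_sum1 <- de_sum0 <- lb_sum1 <- lb_sum0 <- numeric(n_iter)
    for (b in usable) {
      q <- quotas[[b]]
      if (q == 0) next
      s1 <- matrix(sample(idx1[[b]], q * n_iter, replace = TRUE), nrow = n_iter)
      s0 <- matrix(sample(idx0[[b]], q * n_iter, replace = TRUE), nrow = n_iter)
      de_sum1 <- de_sum1 + rowSums(matrix(de1[s1], nrow = n_iter))
      de_sum0 <- de_sum0 + rowSums(matrix(de1[s0], nrow = n_iter))
      lb_sum1 <- lb_sum1 + rowSums(matrix(lb[s1], nrow = n_iter))
      lb_sum0 <- lb_sum0 + rowSums(matrix(lb[s0], nrow = n_iter))
    }
  })
  tot <- sum(quotas)
  diffs <- de_sum1 / tot - de_sum0 / tot
  observed <- mean(df$de[df$has_m6a]) - mean(df$de[!df$has_m6a])
  p <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  structure(list(
    observed_diff = observed,
    boot_diffs = diffs,
    p_value = p,
    ci = unname(quantile(diffs, c(0.025, 0.975))),
    matching_quality = mean(abs(lb_sum1 / tot - lb_sum0 / tot)),
    quotas = quotas,
    n_per_group = tot,
    n_iter = n_iter
  ), class = "glori_bootstrap")
}

# Integer allocation preserving the total (largest-remainder rounding).
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    add <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}

#' @export
print.glori_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<glori_bootstrap> diff = %.4f, 95%% CI [%.4f, %.4f], p = %.4g (%d iter)\n",
    x$observed_diff, x$ci[1], x$ci[2], x$p_value, x$n_iter))
  invisible(x)
}

#' Jaccard index of two gene sets
#'
#' @param set_a,set_b character vectors (duplicates ignored).
#' @return `|A intersect B| / |A union B|`; both sets empty is an error.
#' @examples
#' jaccard(letters[1:10], letters[6:25])
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) && !length(set_b))
    stop("Jaccard index undefined for two empty sets", call. = FALSE)
  length(intersect(set_a, set_b)) / length(union(set_a, set_b))
}

#' Permutation test for gene-set overlap
#'
#' Draws `n_perm` pairs of random sets of the observed sizes (without
#' replacement) from the universe and compares their overlap with the
#' observed one. The empirical p uses the add-one rule
#' `(1 + #{perm >= obs}) / (n_perm + 1)`, so it is never zero.
#'
#' @param set_a,set_b gene sets (must be subsets of `universe`).
#' @param universe the gene pool to draw from.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param keep_null keep the permuted overlap counts in the result.
#' @return object of class `glori_overlap`: sizes, `intersection`, `union`,
#'   `jaccard`, `p_value`, `n_perm` (and `null_overlaps` if kept).
#' @export
jaccard_permutation <- function(set_a, set_b, universe, n_perm = 1e6,
                                seed = 1L, keep_null = FALSE) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("sets must be subsets of the universe", call. = FALSE)
  N <- length(universe)
  na <- length(set_a); nb <- length(set_b)
  if (na > N || nb > N) stop("set larger than universe", call. = FALSE)
  obs <- length(intersect(set_a, set_b))
  perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      ia <- sample.int(N, na)
      ib <- sample.int(N, nb)
      na + nb - length(unique(c(ia, ib)))
    }, integer(1))
  })
  structure(list(
    size_a = na, size_b = nb,
    intersection = obs,
    union = length(union(set_a, set_b)),
    jaccard = jaccard(set_a, set_b),
    p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
    n_perm = n_perm,
    null_overlaps = if (keep_null) perm
  ), class = "glori_overlap")
}

#' @export
print.glori_overlap <- function(x, ...) {
  cat(sprintf(
    "<glori_overlap> |A|=%d |B|=%d overlap=%d Jaccard=%.3f p=%.3g (%g perms)\n",
    x$size_a, x$size_b, x$intersection, x$jaccard, x$p_value, x$n_perm))
  invisible(x)
}

#' Upper-tail hypergeometric lineage enrichment test
#'
#' `P(X >= k)` where `X` counts lineage genes in a random sample of size `n`
#' from a population of `N` genes of which `K` belong to the lineage.
#'
#' @param k observed successes (lineage genes among the sample).
#' @param n sample size (co-expressed genes).
#' @param K lineage size in the population.
#' @param N population size.
#' @return the inclusive upper-tail probability.
#' @examples
#' lineage_hypergeometric(k = 4, n = 4, K = 5, N = 10)  # 5/210
#' @export
lineage_hypergeometric <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N)
    stop("infeasible hypergeometric counts", call. = FALSE)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Classify differentially expressed genes by direction
#'
#' Missing `padj` is treated as 1; thresholds are strict
#' (`|log2FC| > lfc_cut`, `padj < padj_cut`).
#'
#' @param de_table tibble with `gene`, `log2FoldChange`, `padj`.
#' @param padj_cut,lfc_cut thresholds.
#' @return list with `up` and `down` character vectors of gene ids.
#' @export
de_gene_classifier <- function(de_table, padj_cut = 1e-5, lfc_cut = 0.5) {
  padj <- ifelse(is.na(de_table$padj), 1, de_table$padj)
  sig <- padj < padj_cut
  list(up = de_table$gene[sig & de_table$log2FoldChange > lfc_cut],
       down = de_table$gene[sig & de_table$log2FoldChange < -lfc_cut])
}
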