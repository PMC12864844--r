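#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the sequence-context score model
#'
#' One row per one-hot context feature with its normalised importance.
#'
#' @param x a [fit_score_model()] result.
#' @param ... unused.
#' @return tibble `feature`, `offset`, `base`, `importance`.
#' @method tidy glori_score_model
#' @export
tidy.glori_score_model <- function(x, ...) {
  nm <- names(x$importance)
  tibble(feature = nm,
         offset = as.integer(sub("^p(-?\\d+)_.*$", "\\1", nm)),
         base = sub("^p-?\\d+_", "", nm),
         importance = unname(x$importance))
}

#' @rdname tidy.glori_score_model
#' @return `glance()`: one-row tibble of fit metrics.
#' @method glance glori_score_model
#' @export
glance.glori_score_model <- function(x, ...) {
  tibble(n_sites = x$n_sites, mse_train = x$mse_train,
         mse_test = x$mse_test, r2_test = x$r2_test, r2_full = x$r2_full,
         nrounds = x$params$nrounds, max_depth = x$params$max_depth,
         eta = x$params$eta, seed = x$params$seed)
}

#' Tidy the expression-matched bootstrap
#'
#' @param x a [expression_matched_bootstrap()] result.
#' @param ... unused.
#' @return `tidy()`: the bootstrap distribution, one row per iteration;
#'   `glance()`: a one-row summary.
#' @method tidy glori_bootstrap
#' @export
tidy.glori_bootstrap <- function(x, ...) {
  tibble(iteration = seq_along(x$boot_diffs), diff = x$boot_diffs)
}

#' @rdname tidy.glori_bootstrap
#' @method glance glori_bootstrap
#' @export
glance.glori_bootstrap <- function(x, ...) {
  tibble(observed_diff = x$observed_diff, p_value = x$p_value,
         ci_lower = x$ci[1], ci_upper = x$ci[2],
         matching_quality = x$matching_quality,
         n_per_group = x$n_per_group, n_iter = x$n_iter)
}

#' Tidy the overlap permutation result
#'
#' @param x a [jaccard_permutation()] result.
#' @param ... unused.
#' @return one-row tibble of the overlap statistics.
#' @method glance glori_overlap
#' @export
glance.glori_overlap <- function(x, ...) {
  tibble(size_a = x$size_a, size_b = x$size_b,
         intersection = x$intersection, union = x$union,
         jaccard = x$jaccard, p_value = x$p_value, n_perm = x$n_perm)
}
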