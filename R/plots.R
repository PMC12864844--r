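#' Plot a metagene profile
#'
#' Bar chart of site counts per 5'-to-3' bin.
#'
#' @param object a [metagene()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot glori_metagene
#' @export
autoplot.glori_metagene <- function(object, ...) {
  ggplot2::ggplot(object$bin_counts,
                  ggplot2::aes(x = factor(.data$bin), y = .data$n)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "transcript bin (5' to 3')", y = "m6A sites",
                  title = "Metagene distribution of m6A sites") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.glori_metagene
#' @param mg a [metagene()] result.
#' @export
plot_metagene <- function(mg, ...) autoplot.glori_metagene(mg, ...)

#' Plot the linkage p-value distribution
#'
#' Histogram of per-pair independence-test p-values; a flat histogram
#' indicates no single-molecule co-methylation.
#'
#' @param object a [linkage_survey()] result.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot glori_linkage_survey
#' @export
autoplot.glori_linkage_survey <- function(object, bins = 20, ...) {
  ggplot2::ggplot(tibble(p = object$p_values), ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey30") +
    ggplot2::labs(x = "linkage p-value", y = "site pairs",
                  title = sprintf("Adjacent-site linkage (KS = %.3f)",
                                  object$ks_statistic)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.glori_linkage_survey
#' @param survey a [linkage_survey()] result.
#' @export
plot_linkage_pvalues <- function(survey, bins = 20) {
  autoplot.glori_linkage_survey(survey, bins = bins)
}

#' Plot positional importance of the sequence-context model
#'
#' @param object a [fit_score_model()] result.
#' @param ... unused.
#' @return a ggplot of summed importance per site-relative offset.
#' @method autoplot glori_score_model
#' @export
autoplot.glori_score_model <- function(object, ...) {
  imp <- position_importance(object)
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$offset, y = .data$importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = imp$offset) +
    ggplot2::labs(x = "position relative to m6A site",
                  y = "importance (gain)",
                  title = "Sequence-context model importance") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.glori_score_model
#' @param model a [fit_score_model()] result.
#' @export
plot_position_importance <- function(model) autoplot.glori_score_model(model)

#' Plot the bootstrap distribution of DE-proportion differences
#'
#' @param object a [expression_matched_bootstrap()] result.
#' @param ... unused.
#' @return a ggplot with the 95% CI and observed difference marked.
#' @method autoplot glori_bootstrap
#' @export
autoplot.glori_bootstrap <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$diff)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$ci, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$observed_diff,
                        colour = "firebrick") +
    ggplot2::labs(x = "DE proportion difference (m6A - non-m6A)",
                  y = "iterations",
                  title = "Expression-matched bootstrap") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sequence logo from an information-content matrix
#'
#' Stacked-bar rendering of per-position letter heights (bits).
#'
#' @param heights a [logo_matrix()] result.
#' @return a ggplot.
#' @export
plot_logo <- function(heights) {
  df <- as_tibble(as.data.frame.table(heights, responseName = "bits"))
  names(df)[1:2] <- c("offset", "base")
  df$offset <- as.integer(as.character(df$offset))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$bits,
                                   fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(breaks = unique(df$offset)) +
    ggplot2::labs(x = "position relative to m6A site",
                  y = "information content (bits)") +
    ggplot2::theme_minimal()
}
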