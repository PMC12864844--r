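#' Extract the 13-nt sequence context around each site
#'
#' Six nucleotides upstream and downstream of the site (centre always the
#' adenosine), N-padded where the window runs past a transcript end.
#'
#' @param sites tibble with `gene_id`, `pos`.
#' @param transcripts tibble with `gene_id`, `sequence`.
#' @param flank flank width (6 gives the 13-nt window).
#' @return `sites` with a `context13` column.
#' @export
extract_context <- function(sites, transcripts, flank = 6L) {
  sites$context13 <- context_at(transcripts, sites$gene_id, sites$pos, flank)
  sites
}

#' Composition of the +1 base stratified by score band
#'
#' @param sites tibble with `context13` and a score column.
#' @param score_col name of the score column.
#' @param breaks band boundaries; bands are `(b[i], b[i+1]]` built from
#'   `c(-Inf, breaks, Inf)`.
#' @return tibble `band`, `base`, `n`, `freq` (frequencies sum to 1 within a
#'   band; empty bands are absent).
#' @export
plus1_composition <- function(sites, score_col = "score",
                              breaks = c(0.1, 0.5, 0.9)) {
  flank <- (nchar(sites$context13[1]) - 1L) / 2L
  sites |>
    dplyr::mutate(
      band = cut(.data[[score_col]], c(-Inf, breaks, Inf)),
      plus1 = substr(.data$context13, flank + 2L, flank + 2L)) |>
    dplyr::count(.data$band, base = .data$plus1) |>
    dplyr::group_by(.data$band) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Position-by-base information-content matrix for sequence logos
#'
#' Per position, letter heights `f_b * IC` where
#' `IC = 2 + sum_b f_b log2 f_b` bits under a uniform background; `N`s are
#' ignored when computing frequencies. Row sums equal the positional IC.
#'
#' @param contexts character vector of equal-length contexts.
#' @return numeric matrix (positions x ACGU) of letter heights in bits, with
#'   attribute `"ic"` (the positional information content) and row names
#'   giving site-relative offsets.
#' @export
logo_matrix <- function(contexts) {
  stopifnot(length(contexts) >= 1)
  k <- nchar(contexts[1])
  mat <- matrix(utf8ToInt(paste(contexts, collapse = "")),
                ncol = k, byrow = TRUE)
  heights <- matrix(0, k, 4, dimnames = list(
    as.character(seq_len(k) - 1L - (k - 1L) %/% 2L), .RNA_BASES))
  ic <- numeric(k)
  codes <- utf8ToInt(paste(.RNA_BASES, collapse = ""))
  for (j in seq_len(k)) {
    col <- mat[, j]
    col <- col[col != .CODE_N]
    if (!length(col)) next
    f <- tabulate(match(col, codes), 4) / length(col)
    h <- sum(ifelse(f > 0, f * log2(f), 0))
    ic[j] <- 2 + h
    heights[j, ] <- f * ic[j]
  }
  attr(heights, "ic") <- ic
  heights
}

#' One-hot encode fixed-width sequence contexts
#'
#' Produces the `positions x 4` binary feature block per context (13-nt
#' contexts give 52 columns, named `p<offset>_<base>`); an `N` yields an
#' all-zero block at its position.
#'
#' @param contexts character vector of equal-length contexts.
#' @return binary matrix with one row per context.
#' @export
one_hot_contexts <- function(contexts) {
  k <- nchar(contexts[1])
  n <- length(contexts)
  mat <- matrix(utf8ToInt(paste(contexts, collapse = "")),
                ncol = k, byrow = TRUE)
  codes <- utf8ToInt(paste(.RNA_BASES, collapse = ""))
  offs <- seq_len(k) - 1L - (k - 1L) %/% 2L
  X <- matrix(0, n, 4L * k,
              dimnames = list(NULL, paste0(
                "p", rep(offs, each = 4L), "_", rep(.RNA_BASES, k))))
  for (j in seq_len(k)) {
    hit <- match(mat[, j], codes)
    ok <- !is.na(hit)
    X[cbind(which(ok), (j - 1L) * 4L + hit[ok])] <- 1
  }
  X
}

# Inverse of one_hot_contexts (all-zero blocks decode to N).
decode_one_hot <- function(X) {
  k <- ncol(X) / 4L
  apply(X, 1, function(row) {
    paste(vapply(seq_len(k), function(j) {
      block <- row[(j - 1L) * 4L + 1:4]
      if (sum(block) == 0) "N" else .RNA_BASES[which.max(block)]
    }, character(1)), collapse = "")
  })
}

#' Assemble the design matrix linking sequence context to site scores
#'
#' @param sites tibble with `context13`, a score column, and optionally
#'   coverage and `eij_distance` columns.
#' @param score_col,cov_col column names for the regression target and the
#'   coverage filter.
#' @return object of class `glori_context_matrix`: list with `sites`, `X`
#'   (one-hot matrix), `y`, `coverage`, `eij_distance`.
#' @export
context_matrix <- function(sites, score_col = "median_control",
                           cov_col = NULL) {
  structure(list(
    sites = sites,
    X = one_hot_contexts(sites$context13),
    y = sites[[score_col]],
    coverage = if (!is.null(cov_col)) sites[[cov_col]],
    eij_distance = sites$eij_distance %||% rep(NA_real_, nrow(sites))
  ), class = "glori_context_matrix")
}

#' Gradient-boosted regression of site scores on sequence context
#'
#' Fits a gradient-boosted tree ensemble (squared-error objective; defaults
#' 300 rounds, depth 3, learning rate 0.1, single-threaded for determinism)
#' from the one-hot 13-nt context to the site score, after dropping sites
#' below the coverage floor. Performance is reported as train/test MSE and
#' R-squared on a held-out split; predictions and their percentile ranks are
#' produced for the full filtered dataset, and per-feature importances
#' (gain, normalised to sum 1 over all 52 context features) quantify which
#' positions carry the signal.
#'
#' @param cm a [context_matrix()].
#' @param min_cov coverage floor (rows below it are dropped; ignored when the
#'   matrix has no coverage).
#' @param test_frac held-out fraction.
#' @param seed integer seed controlling the split and the fit.
#' @param nrounds,max_depth,eta boosting hyperparameters.
#' @param min_sites minimum qualifying sites.
#' @return object of class `glori_score_model`; see [tidy.glori_score_model()]
#'   and [glance.glori_score_model()].
#' @export
fit_score_model <- function(cm, min_cov = 40, test_frac = 0.2, seed = 1L,
                            nrounds = 300, max_depth = 3, eta = 0.1,
                            min_sites = 200) {
  stopifnot(inherits(cm, "glori_context_matrix"))
  keep <- if (is.null(cm$coverage)) rep(TRUE, length(cm$y))
          else !is.na(cm$coverage) & cm$coverage >= min_cov
  keep <- keep & !is.na(cm$y)
  n <- sum(keep)
  if (n < min_sites)
    stop("only ", n, " qualifying sites (need >= ", min_sites, ")",
         call. = FALSE)
  X <- cm$X[keep, , drop = FALSE]
  y <- cm$y[keep]
  test_idx <- withr::with_seed(as.integer(seed),
                               sort(sample.int(n, round(test_frac * n))))
  train_idx <- setdiff(seq_len(n), test_idx)
  dtrain <- xgboost::xgb.DMatrix(X[train_idx, , drop = FALSE],
                                 label = y[train_idx], nthread = 1)
  booster <- withr::with_seed(as.integer(seed), xgboost::xgb.train(
    params = xgboost::xgb.params(objective = "reg:squarederror",
                                 max_depth = max_depth, learning_rate = eta,
                                 nthread = 1, seed = as.integer(seed)),
    data = dtrain, nrounds = nrounds, verbose = 0))
  pred_all <- stats::predict(booster, xgboost::xgb.DMatrix(X, nthread = 1))
  mse <- function(obs, fit) mean((obs - fit)^2)
  r2 <- function(obs, fit) 1 - sum((obs - fit)^2) / sum((obs - mean(obs))^2)
  imp_tab <- xgboost::xgb.importance(model = booster)
  importance <- setNames(rep(0, ncol(X)), colnames(X))
  importance[imp_tab$Feature] <- imp_tab$Gain
  importance <- importance / sum(importance)
  predictions <- cm$sites[keep, , drop = FALSE]
  predictions$observed <- y
  predictions$predicted <- pred_all
  predictions$pred_percentile <- rank(pred_all) / length(pred_all)
  predictions$eij_distance <- cm$eij_distance[keep]
  structure(list(
    booster = booster,
    mse_train = mse(y[train_idx], pred_all[train_idx]),
    mse_test = mse(y[test_idx], pred_all[test_idx]),
    r2_test = r2(y[test_idx], pred_all[test_idx]),
    r2_full = r2(y, pred_all),
    importance = importance,
    predictions = predictions,
    test_idx = test_idx,
    n_sites = n,
    params = list(min_cov = min_cov, test_frac = test_frac, seed = seed,
                  nrounds = nrounds, max_depth = max_depth, eta = eta)
  ), class = "glori_score_model")
}

#' @export
print.glori_score_model <- function(x, ...) {
  cat("<glori_score_model>", x$n_sites, "sites;",
      sprintf("test MSE %.4f, test R2 %.3f\n", x$mse_test, x$r2_test))
  invisible(x)
}

#' Importance mass per context position
#'
#' Sums the per-feature importances of a fitted score model over the four
#' bases at each site-relative offset.
#'
#' @param model a [fit_score_model()] result.
#' @return tibble `offset`, `importance`.
#' @export
position_importance <- function(model) {
  nm <- names(model$importance)
  off <- as.integer(sub("^p(-?\\d+)_.*$", "\\1", nm))
  tibble(offset = off, importance = model$importance) |>
    dplyr::group_by(.data$offset) |>
    dplyr::summarise(importance = sum(.data$importance), .groups = "drop")
}

#' Contrast predicted-high sites by their observed score
#'
#' Takes the sites in the top `top_frac` of predicted scores and splits them
#' into a "coherent" group (observed score > `hi`) and a "low score" group
#' (observed < `lo`), then compares the groups' distances to the nearest
#' exon-intron junction. With junction-proximal methylation suppression, the
#' low-score group sits closer to junctions than the coherent group.
#'
#' @param model a [fit_score_model()] result (its `predictions` must carry
#'   `eij_distance`).
#' @param top_frac predicted-score percentile cut (0.01 = top 1%).
#' @param hi,lo observed-score cuts for the two groups.
#' @return list with `groups` (tibble with a `group` column), `median_eij`
#'   (named numeric, per group) and `n` (group sizes).
#' @export
predicted_vs_observed_contrast <- function(model, top_frac = 0.01, hi = 0.8,
                                           lo = 0.1) {
  pred <- model$predictions
  top <- dplyr::filter(pred, .data$pred_percentile >= 1 - top_frac)
  top$group <- dplyr::case_when(
    top$observed > hi ~ "coherent",
    top$observed < lo ~ "low_score",
    TRUE ~ NA_character_)
  groups <- dplyr::filter(top, !is.na(.data$group))
  med <- tapply(groups$eij_distance, groups$group, median, na.rm = TRUE)
  n <- table(groups$group)
  for (g in c("coherent", "low_score")) {
    if (!g %in% names(med)) {
      message("group '", g, "' is empty")
    }
  }
  list(groups = groups,
       median_eij = med,
       n = n)
}
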