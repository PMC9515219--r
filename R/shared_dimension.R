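#' Extract the shared disease dimension from an effect matrix
#'
#' Principal component analysis of the regions x conditions effect-size
#' matrix. Component 1 — the shared dimension — is the axis of region-wise
#' covariation common to all conditions. By default columns are centered but
#' not scaled (`scaling_mode = "center"`); `"zscore"` additionally scales
#' each condition to unit variance. Both modes are exposed because the
#' variance-explained figure depends on the choice.
#'
#' Eigenvector signs are arbitrary, so a fixed orientation rule is applied:
#' each component is oriented so that its correlation with the row-mean
#' (mean-effect) map is positive; that way regions with the most negative
#' mean effect receive negative scores. A component uncorrelated with the
#' mean map (|r| < 1e-12) is oriented so its largest-magnitude loading is
#' positive.
#'
#' @param effects an [effect_matrix()] (>= 2 conditions, >= 3 regions, no
#'   masked values).
#' @param scaling_mode `"center"` (default) or `"zscore"`.
#' @param n_components number of components to retain (default: all).
#' @return An object of class `shared_dimension_result` with fields
#'   `scores` (regions x components), `loadings` (conditions x components),
#'   `variance_explained`, `scaling_mode`, `orientation`, `meta`.
#' @export
fit_shared_dimension <- function(effects, scaling_mode = c("center", "zscore"),
                                 n_components = NULL) {
  scaling_mode <- match.arg(scaling_mode)
  stopifnot(inherits(effects, "effect_matrix"))
  X <- effects$values
  if (ncol(X) < 2L) stopf("need at least 2 conditions to extract a shared dimension")
  if (nrow(X) < 3L) stopf("need at least 3 regions")
  if (any(!is.finite(X)))
    stopf("effect matrix has masked values; restrict regions with align_sources() first")
  if (all(apply(X, 2L, stats::sd) < 1e-14))
    stopf("effect matrix is constant; no variance to decompose")
  if (scaling_mode == "zscore" && any(apply(X, 2L, stats::sd) < 1e-14))
    stopf("a condition has zero variance; cannot z-score")
  pc <- stats::prcomp(X, center = TRUE, scale. = (scaling_mode == "zscore"))
  k <- n_components %||% ncol(pc$x)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  rmean <- rowMeans(X)
  flips <- vapply(seq_len(k), function(j) {
    r <- suppressWarnings(stats::cor(scores[, j], rmean))
    if (is.finite(r) && abs(r) > 1e-12) r < 0
    else loadings[which.max(abs(loadings[, j])), j] < 0
  }, logical(1L))
  scores[, flips] <- -scores[, flips, drop = FALSE]
  loadings[, flips] <- -loadings[, flips, drop = FALSE]
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  rownames(scores) <- effects$meta$region_id
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve, scaling_mode = scaling_mode,
                 orientation = "positive correlation with the mean-effect map",
                 meta = effects$meta),
            class = "shared_dimension_result")
}

#' @export
print.shared_dimension_result <- function(x, ...) {
  cat(sprintf("shared_dimension_result: %d components over %d regions (%s)\n",
              ncol(x$scores), nrow(x$scores), x$scaling_mode))
  cat("variance explained:", paste(sprintf("%.1f%%", 100 * x$variance_explained),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Extract one component's score map
#'
#' @param result a `shared_dimension_result`.
#' @param component component index (default 1, the shared dimension).
#' @return A [parcel_map()] of component scores.
#' @export
scores_map <- function(result, component = 1L) {
  parcel_map(result$scores[, component], result$meta,
             name = colnames(result$scores)[component])
}

#' Mean effect map across conditions
#'
#' Row-wise arithmetic mean of the effect matrix; a model-free companion to
#' the shared dimension.
#'
#' @param effects an [effect_matrix()] with no masked values.
#' @return A [parcel_map()].
#' @export
mean_effect_map <- function(effects) {
  stopifnot(inherits(effects, "effect_matrix"))
  if (any(!is.finite(effects$values)))
    stopf("effect matrix has masked values; restrict regions with align_sources() first")
  parcel_map(rowMeans(effects$values), effects$meta, name = "mean_effect")
}

#' Leave-one-condition-out sensitivity of the shared dimension
#'
#' Refits the shared dimension with each condition held out in turn and
#' reports the absolute correlation of the refit component-1 scores with the
#' reference scores (sign-invariant, since eigenvector orientation can flip
#' under refitting).
#'
#' @param effects an [effect_matrix()] with >= 3 conditions.
#' @param reference a `shared_dimension_result` to compare against; defaults
#'   to the fit on all conditions.
#' @param scaling_mode passed to [fit_shared_dimension()].
#' @return A data.frame with one row per held-out condition: `condition`,
#'   `similarity` (|r|), `variance_explained` of the refit first component.
#' @export
leave_one_condition_out <- function(effects, reference = NULL,
                                    scaling_mode = c("center", "zscore")) {
  scaling_mode <- match.arg(scaling_mode)
  stopifnot(inherits(effects, "effect_matrix"))
  if (ncol(effects$values) < 3L)
    stopf("leave-one-condition-out needs at least 3 conditions")
  if (is.null(reference))
    reference <- fit_shared_dimension(effects, scaling_mode = scaling_mode)
  ref1 <- reference$scores[, 1L]
  rows <- lapply(seq_along(effects$conditions), function(j) {
    sub <- effect_matrix(effects$values[, -j, drop = FALSE], effects$meta,
                         effects$conditions[-j])
    fit <- fit_shared_dimension(sub, scaling_mode = scaling_mode, n_components = 1L)
    data.frame(condition = effects$conditions[j],
               similarity = abs(stats::cor(fit$scores[, 1L], ref1)),
               variance_explained = fit$variance_explained[1L])
  })
  do.call(rbind, rows)
}
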