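std_stats <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1          # constant features pass through unscaled
  list(mu = mu, sd = sdv)
}

apply_std <- function(X, st) sweep(sweep(X, 2L, st$mu, `-`), 2L, st$sd, `/`)

balanced_folds <- function(n, k) {
  if (n < 2L * k) stopf("cannot form %d folds of >= 2 regions from %d regions", k, n)
  sample(rep(seq_len(k), length.out = n))
}

lasso_grid <- function(Xs, y, n_lambda = 100L) {
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / nrow(Xs)
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * 1e-4), length.out = n_lambda))
}

# one nested-CV pass over the regions; returns out-of-fold predictions and
# the per-outer-fold support of the refit models
nested_cv_once <- function(X, y, k_outer, k_inner) {
  n <- nrow(X); p <- ncol(X)
  fold <- balanced_folds(n, k_outer)
  yhat <- rep(NA_real_, n)
  support <- matrix(FALSE, k_outer, p)
  for (f in seq_len(k_outer)) {
    tr <- which(fold != f); te <- which(fold == f)
    st <- std_stats(X[tr, , drop = FALSE])
    Xtr <- apply_std(X[tr, , drop = FALSE], st)
    grid <- lasso_grid(Xtr, y[tr])
    inner <- balanced_folds(length(tr), k_inner)
    mae <- matrix(NA_real_, k_inner, length(grid))
    for (g in seq_len(k_inner)) {
      itr <- tr[inner != g]; ite <- tr[inner == g]
      sti <- std_stats(X[itr, , drop = FALSE])
      fit <- glmnet::glmnet(apply_std(X[itr, , drop = FALSE], sti), y[itr],
                            alpha = 1, lambda = grid, standardize = FALSE)
      pred <- stats::predict(fit, newx = apply_std(X[ite, , drop = FALSE], sti),
                             s = grid)
      mae[g, ] <- colMeans(abs(pred - y[ite]))
    }
    best <- which.min(colMeans(mae))    # ties resolve to the larger penalty
    refit <- glmnet::glmnet(Xtr, y[tr], alpha = 1, lambda = grid,
                            standardize = FALSE)
    beta <- as.numeric(stats::coef(refit, s = grid[best]))[-1L]
    support[f, ] <- beta != 0
    yhat[te] <- as.numeric(stats::predict(refit,
      newx = apply_std(X[te, , drop = FALSE], st), s = grid[best]))
  }
  list(yhat = yhat, support = support, fold = fold)
}

#' Nested cross-validated LASSO prediction of a target map
#'
#' Predicts a target parcel map from a multiscale feature panel with
#' five-fold nested cross-validation: per repeat, regions are split into
#' `k_outer` outer folds; within each outer training partition an inner
#' `k_inner`-fold cross-validation selects the L1 penalty with the lowest
#' inner mean absolute error from a 100-value log-spaced grid running from
#' the data-derived maximal penalty down to 1e-4 of it. Features are
#' standardized with training-fold statistics only (inner fits use
#' inner-training statistics), the intercept is unpenalized, the selected
#' model is refit on the full outer training partition and evaluated on the
#' held-out outer fold. Per repeat, the correlation r and MAE between the
#' assembled out-of-fold predictions and the target are recorded; feature
#' selection frequency is the fraction of (outer fold x repeat) refit models
#' with a nonzero coefficient.
#'
#' @param panel a [feature_panel()] (>= 20 regions).
#' @param target the [parcel_map()] to predict (non-constant, unmasked).
#' @param k_outer,k_inner outer/inner fold counts (default 5 and 5).
#' @param n_repeats repetitions with fresh fold assignments (default 100).
#' @param seed integer seed; the full result is deterministic given it.
#' @return An object of class `prediction_result`: `r` and `mae` per repeat,
#'   `selection_frequency` per feature, `n_repeats`, `seed`, `p_perm` (NA
#'   until [permutation_test_prediction()] fills it).
#' @export
nested_lasso_predict <- function(panel, target, k_outer = 5L, k_inner = 5L,
                                 n_repeats = 100L, seed = 1L) {
  stopifnot(inherits(panel, "feature_panel"), inherits(target, "parcel_map"))
  X <- panel$values
  y <- target$values
  if (nrow(X) < 20L) stopf("prediction needs at least 20 regions")
  if (any(!is.finite(X)) || any(!is.finite(y))) stopf("masked values; align first")
  if (stats::sd(y) == 0) stopf("constant target")
  if (ncol(X) == 1L) X <- cbind(X, .pad = 0)   # glmnet needs >= 2 columns
  p <- ncol(panel$values)
  r_rep <- mae_rep <- numeric(n_repeats)
  sel <- matrix(FALSE, 0L, p)
  for (rep in seq_len(n_repeats)) {
    res <- with_seed(child_seed(seed, rep), nested_cv_once(X, y, k_outer, k_inner))
    # an all-intercept model yields constant predictions; score those r = 0
    r_rep[rep] <- if (stats::sd(res$yhat) > 0) stats::cor(y, res$yhat) else 0
    mae_rep[rep] <- mean(abs(y - res$yhat))
    sel <- rbind(sel, res$support[, seq_len(p), drop = FALSE])
  }
  freq <- colMeans(sel)
  names(freq) <- panel$features
  structure(list(r = r_rep, mae = mae_rep, selection_frequency = freq,
                 n_repeats = n_repeats, k_outer = k_outer, k_inner = k_inner,
                 seed = as.integer(seed), p_perm = NA_real_),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: r = %.3f +/- %.3f, MAE = %.3f +/- %.3f (%d repeats)\n",
              mean(x$r), stats::sd(x$r), mean(x$mae), stats::sd(x$mae), x$n_repeats))
  if (!is.na(x$p_perm)) cat(sprintf("permutation p = %.4g\n", x$p_perm))
  invisible(x)
}

#' Region-shuffling permutation test of prediction performance
#'
#' Builds a null distribution of the mean out-of-fold correlation by
#' randomly shuffling the target across regions and rerunning the nested
#' LASSO procedure (with `reduced_repeats` repeats per shuffle, since the
#' null location is insensitive to the repeat count), then reports the
#' one-tailed p-value `(1 + #\{r_null >= r_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams nested_lasso_predict
#' @param n_perm number of target shuffles (default 1000).
#' @param reduced_repeats repeats per shuffle (default 1).
#' @param observed an existing `prediction_result` for the unshuffled
#'   target; computed (with `n_repeats` repeats) if omitted.
#' @param n_repeats repeats for the observed statistic when `observed` is
#'   omitted (default 100).
#' @return The `observed` result with `p_perm` filled in and the null
#'   distribution attached as `null_r`.
#' @export
permutation_test_prediction <- function(panel, target, n_perm = 1000L, seed = 1L,
                                        reduced_repeats = 1L, observed = NULL,
                                        k_outer = 5L, k_inner = 5L,
                                        n_repeats = 100L) {
  if (is.null(observed))
    observed <- nested_lasso_predict(panel, target, k_outer, k_inner,
                                     n_repeats, seed)
  r_obs <- mean(observed$r)
  n <- length(target$values)
  null_r <- vapply(seq_len(n_perm), function(i) {
    y_perm <- with_seed(child_seed(seed, 5000L + i), sample(target$values))
    shuffled <- parcel_map(y_perm, target$meta, name = "shuffled")
    res <- nested_lasso_predict(panel, shuffled, k_outer, k_inner,
                                n_repeats = reduced_repeats,
                                seed = child_seed(seed, 9000L + i))
    mean(res$r)
  }, numeric(1L))
  observed$p_perm <- (1 + sum(null_r >= r_obs)) / (1 + n_perm)
  observed$null_r <- null_r
  observed
}
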