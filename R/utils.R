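`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  invisible(x)
}

# Pearson correlation between a vector and each column of a matrix,
# vectorised; used in spin nulls where cor() per column would dominate runtime.
col_cor <- function(y, X) {
  y <- y - mean(y)
  Xc <- sweep(X, 2L, colMeans(X), `-`)
  num <- as.vector(crossprod(Xc, y))
  den <- sqrt(colSums(Xc^2) * sum(y^2))
  num / den
}

# deterministic child seed derivation, kept below 2^31
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(k) * 7L + 13L
}
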