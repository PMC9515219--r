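# Independent brute-force oracles used across the suite. Each one is written
# from the defining formula, not from the package's code path.

# central-moment profile statistics, one profile at a time
bf_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(mean = mu,
    sd = sqrt(sum((x - mu)^2) / (n - 1)),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0)
}

# partial correlation of profile rows i, j given control vector z, via
# explicit regression residuals
bf_partial_cor <- function(X, z) {
  n <- nrow(X)
  res <- t(apply(X, 1L, function(x) stats::resid(stats::lm(x ~ z))))
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- stats::cor(res[i, ], res[j, ])
  out
}

# Benjamini-Hochberg by the min-over-suffix definition
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# PCA by eigendecomposition of the covariance of the centered/scaled matrix
bf_pca <- function(X, scale. = FALSE) {
  Xc <- scale(X, center = TRUE, scale = scale.)
  S <- crossprod(Xc) / (nrow(Xc) - 1)
  e <- eigen(S, symmetric = TRUE)
  list(scores = Xc %*% e$vectors, loadings = e$vectors,
       variance_explained = e$values / sum(e$values))
}

# diffusion operator spectrum via plain (nonsymmetric) eigen of the
# row-stochastic matrix
bf_diffusion <- function(W, alpha = 0.5, n_components = 5L) {
  d <- rowSums(W)
  Wn <- W / outer(d^alpha, d^alpha)
  P <- Wn / rowSums(Wn)
  e <- eigen(P)
  idx <- order(Re(e$values), decreasing = TRUE)
  list(values = Re(e$values)[idx][seq_len(n_components + 1L)][-1L],
       vectors = Re(e$vectors)[, idx, drop = FALSE][, seq_len(n_components + 1L)][, -1L, drop = FALSE])
}

# align oracle vector u to v in sign and scale before comparing directions
align_to <- function(u, v) u * sum(u * v) / sum(u * u)

tiny_meta <- function(n_per_hemi = 5L) make_parcellation(n_per_hemi)

rand_profiles <- function(meta, n_depths = 10L, seed = 1L, positive = TRUE) {
  set.seed(seed)
  X <- matrix(stats::rnorm(length(meta$region_id) * n_depths),
              length(meta$region_id))
  if (positive) X <- X + 10
  profile_set(X, meta)
}
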