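#' Microstructural profile covariance (MPC)
#'
#' Pairwise partial correlation of depth-wise intensity profiles between
#' regions, controlling for the average whole-cortex profile — so that two
#' regions are similar only insofar as their laminar intensity patterns
#' covary beyond the cortex-wide trend. Negative partial correlations are
#' set to zero and positive entries r are mapped by `log(r / (1 - r))`
#' (r clipped at 1 - 1e-9; zeros stay zero), then symmetrized with a zero
#' diagonal. A region whose residual profile has (near-)zero variance after
#' removing the mean profile gets a zeroed row/column with a warning.
#'
#' @param profiles a [profile_set()] with >= 3 depths and >= 3 regions.
#' @return A [connectivity_matrix()] of kind `"microstructural"`.
#' @export
build_mpc <- function(profiles) {
  stopifnot(inherits(profiles, "profile_set"))
  X <- profiles$intensities
  if (ncol(X) < 3L) stopf("MPC needs at least 3 depths")
  if (nrow(X) < 3L) stopf("MPC needs at least 3 regions")
  zbar <- colMeans(X)
  R <- mpc_partial_cor(X, zbar)
  degenerate <- attr(R, "degenerate")
  if (any(degenerate)) {
    warnf("zero-variance residual profile; zeroing row/column for: %s",
          paste(profiles$meta$region_id[degenerate], collapse = ", "))
    R[degenerate, ] <- 0
    R[, degenerate] <- 0
  }
  R[R < 0] <- 0
  pos <- R > 0
  R[pos] <- log(pmin(R[pos], 1 - 1e-9) / (1 - pmin(R[pos], 1 - 1e-9)))
  R <- (R + t(R)) / 2
  diag(R) <- 0
  connectivity_matrix(R, profiles$meta, kind = "microstructural")
}

# partial correlation of every profile pair given the control profile z,
# via the first-order partial-correlation identity on the raw correlations
mpc_partial_cor <- function(X, z) {
  n <- nrow(X)
  sds <- apply(X, 1L, stats::sd)
  riz <- suppressWarnings(as.vector(stats::cor(t(X), z)))
  riz[!is.finite(riz)] <- 0
  C <- suppressWarnings(stats::cor(t(X)))
  C[!is.finite(C)] <- 0
  denom <- 1 - riz^2
  degenerate <- sds == 0 | denom <= 1e-12
  den <- sqrt(pmax(outer(denom, denom), 1e-300))
  R <- (C - outer(riz, riz)) / den
  R[degenerate, ] <- 0
  R[, degenerate] <- 0
  R[R > 1] <- 1
  R[R < -1] <- -1
  attr(R, "degenerate") <- degenerate
  R
}

#' Fisher r-to-z transform of a correlation matrix
#'
#' Element-wise `atanh` with entries clipped to +/- (1 - 1e-9); the diagonal
#' is set to zero. Input entries must lie in \[-1, 1\].
#'
#' @param corr a [connectivity_matrix()] (or plain matrix) of correlations.
#' @return Same container type with transformed entries.
#' @export
fisher_z_matrix <- function(corr) {
  V <- if (inherits(corr, "connectivity_matrix")) corr$values else corr
  if (any(abs(V) > 1)) stopf("correlations must lie in [-1, 1]")
  Z <- atanh(pmax(pmin(V, 1 - 1e-9), -(1 - 1e-9)))
  diag(Z) <- 0
  if (inherits(corr, "connectivity_matrix"))
    connectivity_matrix(Z, corr$meta, kind = corr$kind)
  else Z
}

#' Row-wise sparsification of a connectivity matrix
#'
#' Keeps, per row, the `ceiling(density * n)` largest off-diagonal entries
#' and zeroes the rest (including the diagonal). Ties at the threshold break
#' toward the lower column index. The result is generally asymmetric; the
#' downstream angle kernel compares rows, which resolves the asymmetry.
#'
#' @param matrix a [connectivity_matrix()] or plain square matrix.
#' @param density fraction of entries to keep per row, in (0, 1\].
#' @return A plain numeric matrix (not symmetrized).
#' @export
sparsify_rows <- function(matrix, density = 0.1) {
  V <- if (inherits(matrix, "connectivity_matrix")) matrix$values else matrix
  if (density <= 0 || density > 1) stopf("density must lie in (0, 1]")
  n <- ncol(V)
  k <- ceiling(density * n)
  out <- base::matrix(0, n, n, dimnames = dimnames(V))
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    keep <- cand[order(-V[i, cand])[seq_len(min(k, length(cand)))]]
    out[i, keep] <- V[i, keep]
  }
  out
}

#' Normalized-angle affinity between matrix rows
#'
#' `affinity(i, j) = 1 - acos(cosine similarity of rows i and j) / pi`:
#' 1 for identical directions, 0.5 for orthogonal rows, 0 for opposite.
#' Symmetric by construction, unit diagonal.
#'
#' @param matrix a [connectivity_matrix()] or plain square matrix with no
#'   all-zero rows; `meta` required if a plain matrix is given.
#' @param meta optional [parcellation_meta()] (taken from the input if it is
#'   a `connectivity_matrix`).
#' @return A [connectivity_matrix()] of kind `"affinity"`.
#' @export
normalized_angle_affinity <- function(matrix, meta = NULL) {
  V <- if (inherits(matrix, "connectivity_matrix")) matrix$values else matrix
  meta <- meta %||% matrix$meta
  if (is.null(meta)) stopf("meta required for a plain matrix input")
  norms <- sqrt(rowSums(V^2))
  if (any(norms == 0))
    stopf("all-zero row(s): %s", paste(meta$region_id[norms == 0], collapse = ", "))
  cs <- tcrossprod(V / norms)
  cs[cs > 1] <- 1
  cs[cs < -1] <- -1
  A <- 1 - acos(cs) / pi
  diag(A) <- 1
  connectivity_matrix(A, meta, kind = "affinity")
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE] > 0) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Diffusion map embedding of an affinity matrix
#'
#' Estimates connectome gradients: the affinity kernel W is density-
#' normalized as `W' = D^-alpha W D^-alpha` (`alpha` controls the influence
#' of the sampling density: 0 maximal, 1 none), converted to the
#' row-stochastic diffusion operator, and eigendecomposed. The trivial
#' constant eigenvector (eigenvalue 1) is dropped; component k is scaled by
#' `lambda_k / (1 - lambda_k)` when `t = 0` (the automatic-diffusion-time
#' convention) and by `lambda_k^t` otherwise. Each component is
#' sign-oriented so its correlation with the first centroid coordinate axis
#' is positive (an arbitrary but fixed convention; falls back to making the
#' largest-magnitude entry positive when that correlation vanishes).
#'
#' The eigenproblem is solved densely via the symmetric conjugate
#' `D'^-1/2 W' D'^-1/2`, adequate for parcel counts up to a few hundred.
#'
#' @param affinity a symmetric nonnegative [connectivity_matrix()] over a
#'   connected graph.
#' @param alpha density-normalization exponent in \[0, 1\] (default 0.5).
#' @param t diffusion time (default 0, meaning lambda/(1 - lambda) scaling).
#' @param n_components number of gradients to return (default 10, capped at
#'   regions - 1).
#' @return An object of class `gradient_set`: `gradients` (regions x
#'   components), `eigenvalues` (of the diffusion operator, trivial one
#'   excluded), `params`, `meta`.
#' @export
diffusion_map_embedding <- function(affinity, alpha = 0.5, t = 0, n_components = 10L) {
  stopifnot(inherits(affinity, "connectivity_matrix"))
  W <- affinity$values
  if (any(W < 0)) stopf("affinity must be nonnegative")
  comp <- graph_components(W * (1 - diag(nrow(W))))
  if (max(comp) > 1L)
    stopf("affinity graph is disconnected (%d components: sizes %s)",
          max(comp), paste(tabulate(comp), collapse = ", "))
  d <- rowSums(W)
  if (any(d == 0)) stopf("isolated region(s) in affinity")
  Wn <- W / outer(d^alpha, d^alpha)
  dn <- rowSums(Wn)
  S <- Wn / outer(sqrt(dn), sqrt(dn))
  es <- eigen(S, symmetric = TRUE)
  lambda <- es$values
  phi <- es$vectors / sqrt(dn)           # eigenvectors of the row-stochastic operator
  # drop the trivial component (eigenvalue 1, constant eigenvector)
  lambda <- lambda[-1L]
  phi <- phi[, -1L, drop = FALSE]
  k <- min(n_components, ncol(phi))
  lambda <- lambda[seq_len(k)]
  phi <- phi[, seq_len(k), drop = FALSE]
  scale_k <- if (t == 0) lambda / (1 - lambda) else lambda^t
  G <- sweep(phi, 2L, scale_k, `*`)
  xaxis <- affinity$meta$centroid[, 1L]
  for (j in seq_len(k)) {
    r <- suppressWarnings(stats::cor(G[, j], xaxis))
    flip <- if (is.finite(r) && abs(r) > 1e-12) r < 0 else G[which.max(abs(G[, j])), j] < 0
    if (flip) G[, j] <- -G[, j]
  }
  dimnames(G) <- list(affinity$meta$region_id, paste0("gradient", seq_len(k)))
  structure(list(gradients = G, eigenvalues = lambda,
                 params = list(alpha = alpha, t = t, kernel = "normalized_angle"),
                 meta = affinity$meta),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("gradient_set: %d components over %d regions (alpha = %g, t = %g)\n",
              ncol(x$gradients), nrow(x$gradients), x$params$alpha, x$params$t))
  invisible(x)
}

#' Connectivity matrix to gradients, end to end
#'
#' Convenience composition: row sparsification at `density`, normalized-
#' angle affinity, diffusion map embedding. Deterministic for fixed input.
#'
#' @param conn a [connectivity_matrix()].
#' @param density row-sparsification density (default 0.1).
#' @inheritParams diffusion_map_embedding
#' @return A `gradient_set`.
#' @export
connectivity_gradients <- function(conn, density = 0.1, alpha = 0.5, t = 0,
                                   n_components = 10L) {
  sp <- sparsify_rows(conn, density)
  aff <- normalized_angle_affinity(sp, meta = conn$meta)
  diffusion_map_embedding(aff, alpha = alpha, t = t, n_components = n_components)
}
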