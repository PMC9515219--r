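test_that("MPC partial correlations match the regression-residual oracle", {
  meta <- tiny_meta(3)
  for (s in 1:3) {
    set.seed(s)
    X <- matrix(rnorm(6 * 10), 6) + 5
    ours <- transgrad:::mpc_partial_cor(X, colMeans(X))
    oracle <- bf_partial_cor(X, colMeans(X))
    diag(oracle) <- diag(ours)
    expect_equal(unname(ours), oracle, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("MPC output is thresholded, log-transformed, symmetric, zero-diagonal", {
  meta <- tiny_meta(5)
  ps <- rand_profiles(meta, n_depths = 12, seed = 2)
  mpc <- build_mpc(ps)
  A <- mpc$values
  expect_true(all(diag(A) == 0))
  expect_equal(max(abs(A - t(A))), 0)
  # thresholding at zero happens before the log transform, so entries that
  # survive are log(r/(1-r)) with r in (0,1): no entry below log(small) sneaks in
  expect_true(all(A == 0 | is.finite(A)))
  raw <- transgrad:::mpc_partial_cor(ps$intensities, colMeans(ps$intensities))
  pos <- raw > 0 & upper.tri(raw)
  expect_equal(A[upper.tri(A)][pos[upper.tri(pos)]],
               log(raw[pos] / (1 - raw[pos])), tolerance = 1e-10)
})

test_that("identical residual profiles hit the finite correlation cap", {
  meta <- tiny_meta(3)
  set.seed(4)
  X <- matrix(rnorm(6 * 10), 6) + 5
  X[2, ] <- X[1, ]
  mpc <- build_mpc(profile_set(X, meta))
  expect_equal(mpc$values[1, 2], log((1 - 1e-9) / 1e-9), tolerance = 1e-6)
})

test_that("Fisher r-to-z matches arctanh and is odd", {
  meta <- tiny_meta(2)
  R <- matrix(c(1, 0.5, -0.3, 0,
                0.5, 1, 0.2, -0.5,
                -0.3, 0.2, 1, 0.7,
                0, -0.5, 0.7, 1), 4)
  z <- fisher_z_matrix(connectivity_matrix(R, meta, "functional"))
  expect_equal(z$values[1, 2], 0.549306144334055, tolerance = 1e-10)
  expect_equal(z$values[1, 4], 0)
  expect_equal(fisher_z_matrix(-R), -fisher_z_matrix(R), tolerance = 1e-12)
  expect_true(all(diag(z$values) == 0))
  expect_error(fisher_z_matrix(R * 1.5), "\\[-1, 1\\]")
})

test_that("row sparsification keeps exactly the top entries per row", {
  meta <- tiny_meta(5)
  set.seed(6)
  V <- matrix(runif(100), 10)
  V <- (V + t(V)) / 2
  cm <- connectivity_matrix(V, meta, "functional")
  sp <- sparsify_rows(cm, density = 0.1)
  expect_true(all(rowSums(sp != 0) == 1L))
  # brute-force per-row sort oracle at a larger density
  sp3 <- sparsify_rows(cm, density = 0.3)
  for (i in 1:10) {
    cand <- setdiff(1:10, i)
    keep <- cand[order(-V[i, cand])[1:3]]
    expect_equal(unname(which(sp3[i, ] != 0)), sort(keep))
  }
  full <- sparsify_rows(cm, density = 1)
  off <- !diag(10)
  expect_equal(full[off], V[off])
})

test_that("normalized angle kernel maps aligned/orthogonal/opposite rows to 1/0.5/0", {
  meta <- tiny_meta(2)
  V <- rbind(c(1, 0, 0, 0), c(2, 0, 0, 0), c(0, 3, 0, 0), c(-1, 0, 0, 0))
  aff <- normalized_angle_affinity(V, meta = meta)
  expect_equal(aff$values[1, 2], 1.0)
  expect_equal(aff$values[1, 3], 0.5)
  expect_equal(aff$values[1, 4], 0.0)
  V[2, ] <- 0
  expect_error(normalized_angle_affinity(V, meta = meta), meta$region_id[2])
})

test_that("embedding equals the dense nonsymmetric eigensolver oracle", {
  meta <- make_parcellation(10)
  for (s in 1:10) {
    set.seed(s)
    W <- matrix(runif(400), 20)
    W <- (W + t(W)) / 2
    diag(W) <- 1
    g <- diffusion_map_embedding(connectivity_matrix(W, meta, "affinity"),
                                 n_components = 5)
    oracle <- bf_diffusion(W, alpha = 0.5, n_components = 5)
    expect_equal(g$eigenvalues, oracle$values, tolerance = 1e-8)
    expect_true(all(g$eigenvalues > -1 & g$eigenvalues <= 1))
    for (k in 1:5)
      expect_lt(max(abs(align_to(oracle$vectors[, k], g$gradients[, k]) -
                        g$gradients[, k])), 1e-8)
  }
})

test_that("gradient 1 sign-separates a bridged two-block affinity", {
  meta <- tiny_meta(5)
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 0.9; W[6:10, 6:10] <- 0.9
  diag(W) <- 1
  W[5, 6] <- W[6, 5] <- 0.05
  g <- diffusion_map_embedding(connectivity_matrix(W, meta, "affinity"),
                               n_components = 2)
  s <- sign(g$gradients[, 1])
  expect_true(all(s[1:5] == s[1]) && all(s[6:10] == -s[1]))
})

test_that("embedding is invariant to region relabeling up to sign", {
  meta <- make_parcellation(10)
  set.seed(3)
  W <- matrix(runif(400), 20); W <- (W + t(W)) / 2; diag(W) <- 1
  g <- diffusion_map_embedding(connectivity_matrix(W, meta, "affinity"), n_components = 3)
  perm <- sample(20)
  gp <- diffusion_map_embedding(
    connectivity_matrix(W[perm, perm], subset_meta(meta, perm), "affinity"),
    n_components = 3)
  for (k in 1:3) {
    a <- g$gradients[perm, k]; b <- gp$gradients[, k]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
})

test_that("disconnected affinities are rejected with component sizes", {
  meta <- tiny_meta(3)
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1
  expect_error(diffusion_map_embedding(connectivity_matrix(W, meta, "affinity")),
               "disconnected")
})
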