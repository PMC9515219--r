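test_that("make_parcellation mirrors hemispheres and separates centroids", {
  m1 <- make_parcellation(1)
  expect_equal(length(m1$region_id), 2L)
  expect_equal(m1$centroid[1, ], m1$centroid[2, ] * c(-1, 1, 1),
               ignore_attr = TRUE)

  meta <- make_parcellation(34)
  expect_equal(length(meta$region_id), 68L)
  # brute-force pairwise angular separation
  cosang <- tcrossprod(meta$centroid)
  diag(cosang) <- -1
  expect_true(max(cosang) < 1 - 1e-6)
  expect_identical(make_parcellation(34), meta)   # deterministic
  expect_error(make_parcellation(0), "at least one region")
})

test_that("smooth maps respect the requested autocorrelation scale", {
  meta <- make_parcellation(34)
  nn <- apply(tcrossprod(meta$centroid) - 2 * diag(68), 1L, which.max)
  draws_small <- simulate_smooth_maps(meta, lengthscale = 0.01, seed = 2, n = 200)
  draws_large <- simulate_smooth_maps(meta, lengthscale = 0.6, seed = 2, n = 200)
  nn_cor <- function(D) mean(sapply(seq_len(68), function(i)
    stats::cor(D[i, ], D[nn[i], ])))
  expect_lt(abs(nn_cor(draws_small)), 0.2)
  expect_gt(nn_cor(draws_large), 0.5)
  expect_identical(simulate_smooth_map(meta, 0.6, seed = 7)$values,
                   simulate_smooth_map(meta, 0.6, seed = 7)$values)
})

test_that("effect matrices plant an exactly rank-1 structure at zero noise", {
  meta <- make_parcellation(10)
  s <- simulate_smooth_map(meta, 0.6, seed = 3)
  cfg <- sim_config(n_regions_per_hemisphere = 10, seed = 3, noise_sd = 0)
  em <- simulate_effect_matrix(meta, s, cfg)
  expect_equal(qr(em$values)$rank, 1L)
  for (j in seq_along(cfg$shared_loadings))
    expect_equal(em$values[, j], cfg$shared_loadings[j] * s$values,
                 ignore_attr = TRUE)
  expect_identical(attr(em, "planted_shared"), s$values)
})

test_that("PC1 recovers the planted shared map under moderate noise", {
  meta <- make_parcellation(34)
  for (s in 1:5) {
    sm <- simulate_smooth_map(meta, 0.6, seed = 50 + s)
    em <- simulate_effect_matrix(meta, sm, sim_config(seed = s, noise_sd = 0.35))
    fit <- fit_shared_dimension(em, n_components = 1)
    expect_gt(abs(stats::cor(fit$scores[, 1], sm$values)), 0.95)
  }
})

test_that("simulated profiles carry their planted peak and amplitude", {
  meta <- make_parcellation(10)
  pk <- parcel_map(rep(0.2, 20), meta)
  am <- parcel_map(rep(2, 20), meta)
  ps <- simulate_profiles(meta, pk, am, n_depths = 14, seed = 1, noise_sd = 0)
  argmax_depth <- ps$depth_fractions[apply(ps$intensities, 1, which.max)]
  expect_true(all(abs(argmax_depth - 0.2) <= 1 / 13 + 1e-12))

  flat <- simulate_profiles(meta, pk, parcel_map(rep(0, 20), meta),
                            n_depths = 14, seed = 1, noise_sd = 0)
  expect_true(all(apply(flat$intensities, 1, stats::sd) <= 1e-12))
  expect_error(simulate_profiles(meta, pk, am, n_depths = 3), "at least 4")
})

test_that("externopyramidization anticorrelates with planted peak depth", {
  meta <- make_parcellation(34)
  set.seed(4)
  pk <- parcel_map(runif(68, 0.05, 0.95), meta)
  am <- parcel_map(rep(2, 68), meta)
  ps <- simulate_profiles(meta, pk, am, n_depths = 18, seed = 2, noise_sd = 0)
  ep <- externopyramidization(ps)
  expect_lt(stats::cor(ep$values, pk$values, method = "spearman"), -0.9)
})

test_that("planted-axis connectivity is block-structured and symmetric", {
  meta <- make_parcellation(5)
  axis <- parcel_map(rep(c(0, 3), each = 5), meta)
  cm <- simulate_connectivity(meta, axis, noise = 0, seed = 1, bandwidth = 1)
  A <- cm$values
  expect_equal(max(abs(A - t(A))), 0)
  expect_true(all(A[1:5, 1:5] == 1) && all(A[6:10, 6:10] == 1))
  off <- A[1:5, 6:10]
  expect_equal(unname(off), matrix(exp(-9 / 2), 5, 5))
})

test_that("gradient 1 of the embedding recovers the planted axis order", {
  meta <- make_parcellation(34)
  for (s in 1:3) {
    ax <- simulate_smooth_map(meta, 0.6, seed = 200 + s)
    cm <- simulate_connectivity(meta, ax, noise = 0, seed = s)
    g <- diffusion_map_embedding(cm)
    expect_gt(abs(stats::cor(g$gradients[, 1], ax$values, method = "spearman")),
              0.95)
  }
})

test_that("feature panels expose their planted support", {
  meta <- make_parcellation(34)
  target <- simulate_smooth_map(meta, 0.6, seed = 9)
  cfg <- sim_config(seed = 9, feature_noise_sd = 0)   # noiseless informative columns
  fp <- simulate_feature_panel(meta, target, cfg)
  expect_equal(dim(fp$values), c(68L, 17L))
  sup <- attr(fp, "planted_support")
  expect_identical(which(sup), 1:3)
  for (j in which(sup))
    expect_equal(stats::cor(fp$values[, j], target$values), 1)
  expect_identical(simulate_feature_panel(meta, target, cfg)$values, fp$values)
})
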