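test_that("identity rotation yields the identity assignment", {
  meta <- make_parcellation(20)
  spins <- generate_spins(meta, rotations = list(diag(3)))
  expect_equal(spins$assignments[1, ], seq_len(40))
})

test_that("spin assignments are valid, hemisphere-preserving and reproducible", {
  meta <- make_parcellation(34)
  spins <- generate_spins(meta, n_rotations = 1000, seed = 5)
  expect_true(all(spins$assignments >= 1 & spins$assignments <= 68))
  hemi <- meta$hemisphere
  # brute-force check of every entry
  src_hemi <- matrix(hemi[spins$assignments], nrow = 1000)
  tgt_hemi <- matrix(rep(hemi, each = 1000), nrow = 1000)
  expect_true(all(src_hemi == tgt_hemi))
  expect_identical(generate_spins(meta, 1000, seed = 5)$assignments,
                   spins$assignments)
})

test_that("spin correlation returns exact self-correlation and bounded p", {
  meta <- make_parcellation(34)
  spins <- generate_spins(meta, 200, seed = 2)
  m <- simulate_smooth_map(meta, 0.6, seed = 3)
  res <- spin_correlation(m, m, spins)
  expect_equal(res$r_observed, 1.0)
  expect_gte(res$p_spin, 1 / 201)
  expect_lte(res$p_spin, 1)
  # under the identity assignment the null r equals r_observed
  id_spins <- generate_spins(meta, rotations = list(diag(3)))
  b <- simulate_smooth_map(meta, 0.6, seed = 4)
  res_id <- spin_correlation(m, b, id_spins)
  expect_equal(res_id$null_distribution[1], res_id$r_observed)
  expect_error(spin_correlation(parcel_map(rep(1, 68), meta), b, spins),
               "zero-variance")
})

test_that("p_spin is invariant to jointly permuting maps and spin table", {
  meta <- make_parcellation(10)
  spins <- generate_spins(meta, 100, seed = 7)
  a <- simulate_smooth_map(meta, 0.6, seed = 1)
  b <- simulate_smooth_map(meta, 0.6, seed = 2)
  res <- spin_correlation(a, b, spins)
  perm <- sample(20)
  meta_p <- subset_meta(meta, perm)
  inv <- order(perm)
  spins_p <- spins
  spins_p$meta <- meta_p
  spins_p$assignments <- matrix(inv[spins$assignments[, perm]], nrow = 100)
  res_p <- spin_correlation(parcel_map(a$values[perm], meta_p),
                            parcel_map(b$values[perm], meta_p), spins_p)
  expect_equal(res_p$r_observed, res$r_observed, tolerance = 1e-12)
  expect_equal(res_p$p_spin, res$p_spin)
})

test_that("BH q-values equal the min-over-suffix brute force", {
  expect_equal(fdr_correct(0.37), 0.37)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(rep(0.2, 6)), rep(0.2, 6))
  for (s in 1:5) {
    set.seed(s)
    p <- runif(23)
    expect_equal(fdr_correct(p), bf_bh(p), tolerance = 1e-12)
  }
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("panel testing flags the target itself and satisfies the BH inequality", {
  meta <- make_parcellation(20)
  spins <- generate_spins(meta, 100, seed = 3)
  target <- simulate_smooth_map(meta, 0.6, seed = 5)
  others <- simulate_smooth_maps(meta, 0.6, seed = 6, n = 4)
  panel <- feature_panel(cbind(target$values, others), meta,
                         features = c("target", paste0("f", 1:4)))
  tab <- test_feature_panel(target, panel, spins)
  expect_equal(tab$r[1], 1.0)
  expect_true(all(tab$q_fdr >= tab$p_spin - 1e-12))
  expect_equal(tab$feature, panel$features)
  expect_equal(dim(attr(tab, "null_distributions")), c(100L, 5L))
})

test_that("a family of null features yields few false discoveries", {
  meta <- make_parcellation(20)
  spins <- generate_spins(meta, 200, seed = 9)
  set.seed(10)
  hits <- replicate(20, {
    target <- parcel_map(rnorm(40), meta)
    panel <- feature_panel(matrix(rnorm(40 * 10), 40), meta)
    sum(test_feature_panel(target, panel, spins)$q_fdr < 0.05)
  })
  expect_lt(mean(hits), 1)
})

test_that("0-100 rescaling is the stated affine map and preserves correlation", {
  meta <- tiny_meta(2)
  m <- parcel_map(c(1, 2, 3, 2.5), meta)
  r <- rescale_0_100(m)
  expect_equal(unname(r$values[1:3]), c(0, 50, 100))
  set.seed(2)
  other <- parcel_map(rnorm(4), meta)
  expect_equal(stats::cor(r$values, other$values),
               stats::cor(m$values, other$values), tolerance = 1e-12)
  expect_error(rescale_0_100(parcel_map(rep(2, 4), meta)), "constant")
})

test_that("stratification matches a brute-force group-by and partitions regions", {
  meta <- make_parcellation(34)
  set.seed(4)
  m <- parcel_map(rnorm(68), meta)
  tab <- stratify_map(m, "community")
  expect_equal(sum(tab$n), 68L)
  for (i in seq_len(nrow(tab))) {
    idx <- meta$community == tab$class[i]
    expect_equal(tab$mean[i], mean(m$values[idx]))
    expect_equal(tab$sd[i], stats::sd(m$values[idx]))
  }
  const <- stratify_map(parcel_map(rep(3.5, 68), meta), "hierarchy")
  expect_true(all(const$mean == 3.5))
})
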