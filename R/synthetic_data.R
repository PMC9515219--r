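#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The defaults define
#' the package's reference study conditions: 68 regions (34 per hemisphere,
#' the granularity of a standard whole-cortex anatomical parcellation), six
#' conditions loading on one shared component with loadings
#' (1, 1, 1, 0.8, 0.8, 0.6), condition noise sized so the shared component
#' carries about half of the total effect variance, spatial autocorrelation
#' lengthscale 0.6 rad, 14 sampling depths for intensity profiles, and a
#' 17-column feature panel (two gradients, five profile features, ten
#' transmitter maps) of which the first three are informative at a
#' signal-to-noise ratio giving a best-case R-squared near 0.5.
#'
#' @param n_regions_per_hemisphere regions per hemisphere (default 34).
#' @param seed integer master seed.
#' @param lengthscale angular correlation scale of smooth maps, radians.
#' @param shared_loadings per-condition loading on the shared map.
#' @param noise_sd SD of the condition-specific smooth noise maps.
#' @param profile_depths number of intracortical sampling depths.
#' @param n_features feature-panel width.
#' @param informative_features indices of panel columns tied to the target.
#' @param effect_beta per-informative-feature coefficient on the target.
#' @param feature_noise_sd SD of i.i.d. noise on informative features.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_regions_per_hemisphere = 34L, seed = 1L,
                       lengthscale = 0.6,
                       shared_loadings = c(1, 1, 1, 0.8, 0.8, 0.6),
                       noise_sd = 0.88, profile_depths = 14L,
                       n_features = 17L, informative_features = 1:3,
                       effect_beta = rep(1, length(informative_features)),
                       feature_noise_sd = sqrt(3)) {
  if (n_regions_per_hemisphere < 1L) stopf("need at least one region per hemisphere")
  if (lengthscale <= 0) stopf("lengthscale must be positive")
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  if (length(shared_loadings) && all(shared_loadings == 0))
    stopf("shared loadings must not all be zero")
  if (length(effect_beta) != length(informative_features))
    stopf("effect_beta must give one coefficient per informative feature")
  structure(list(n_regions_per_hemisphere = as.integer(n_regions_per_hemisphere),
                 seed = as.integer(seed), lengthscale = lengthscale,
                 shared_loadings = shared_loadings, noise_sd = noise_sd,
                 profile_depths = as.integer(profile_depths),
                 n_features = as.integer(n_features),
                 informative_features = as.integer(informative_features),
                 effect_beta = effect_beta,
                 feature_noise_sd = feature_noise_sd),
            class = "sim_config")
}

# evaluate expr under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# golden-angle spiral: n quasi-uniform directions on the +x hemisphere
hemisphere_spiral <- function(n) {
  i <- seq_len(n)
  cospsi <- 1 - (i - 0.5) / n          # uniform area over the half-sphere cap
  sinpsi <- sqrt(pmax(0, 1 - cospsi^2))
  phi <- i * pi * (3 - sqrt(5))
  m <- cbind(cospsi, sinpsi * cos(phi), sinpsi * sin(phi))
  dimnames(m) <- NULL
  m
}

#' Generate a synthetic parcellation
#'
#' Places `n_regions_per_hemisphere` centroids quasi-uniformly on each
#' hemisphere of the unit sphere by a deterministic golden-angle spiral
#' (left hemisphere x < 0, right hemisphere its mirror image through the
#' x = 0 plane). Community labels (7 levels) and hierarchy labels (4 levels)
#' are assigned by the nearest of fixed anchor directions, using the
#' hemisphere-folded coordinate so labels are mirror-symmetric.
#'
#' @param cfg a [sim_config()], or an integer taken as regions per hemisphere.
#' @return A [parcellation_meta()] with 2 x n regions.
#' @export
make_parcellation <- function(cfg = sim_config()) {
  n <- if (is.numeric(cfg)) as.integer(cfg) else cfg$n_regions_per_hemisphere
  if (n < 1L) stopf("need at least one region per hemisphere")
  right <- hemisphere_spiral(n)                     # +x half
  left <- right * matrix(c(-1, 1, 1), n, 3, byrow = TRUE)
  centroid <- rbind(left, right)
  ids <- c(sprintf("lh_region%02d", seq_len(n)), sprintf("rh_region%02d", seq_len(n)))
  hemi <- rep(c("L", "R"), each = n)
  folded <- centroid
  folded[, 1] <- abs(folded[, 1])
  anchors7 <- hemisphere_spiral(7L)
  anchors4 <- hemisphere_spiral(4L)
  community <- paste0("C", max.col(folded %*% t(anchors7)))
  hierarchy <- paste0("H", max.col(folded %*% t(anchors4)))
  parcellation_meta(ids, hemi, centroid, community, hierarchy)
}

# Cholesky factor (upper) of the squared-exponential kernel on great-circle
# distance, with diagonal jitter; cached per call site by the caller.
sq_exp_chol <- function(meta, lengthscale, jitter = 1e-8) {
  cosang <- tcrossprod(meta$centroid)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  theta <- acos(cosang)
  K <- exp(-theta^2 / (2 * lengthscale^2))
  K <- K + diag(jitter, nrow(K))
  R <- tryCatch(chol(K), error = function(e)
    stopf("spatial covariance is not positive definite after jitter (lengthscale %.3g)",
          lengthscale))
  R
}

#' Simulate spatially autocorrelated maps on the sphere
#'
#' Draws from a zero-mean Gaussian process on the region centroids with a
#' squared-exponential kernel of great-circle distance,
#' `k(i, j) = exp(-theta_ij^2 / (2 lengthscale^2))`, plus 1e-8 diagonal
#' jitter. Unit marginal variance; reproducible for a fixed seed.
#'
#' @param meta a [parcellation_meta()].
#' @param lengthscale angular correlation scale in radians (> 0).
#' @param seed integer seed.
#' @param n number of independent maps (for `simulate_smooth_maps`).
#' @return `simulate_smooth_map`: a [parcel_map()]; `simulate_smooth_maps`:
#'   a regions x n numeric matrix.
#' @export
simulate_smooth_map <- function(meta, lengthscale = 0.6, seed = 1L) {
  parcel_map(simulate_smooth_maps(meta, lengthscale, seed, n = 1L)[, 1L], meta,
             name = sprintf("smooth_l%.3g_s%d", lengthscale, as.integer(seed)))
}

#' @rdname simulate_smooth_map
#' @export
simulate_smooth_maps <- function(meta, lengthscale = 0.6, seed = 1L, n = 1L) {
  if (lengthscale <= 0) stopf("lengthscale must be positive")
  R <- sq_exp_chol(meta, lengthscale)
  z <- with_seed(seed, matrix(stats::rnorm(nrow(R) * n), nrow(R), n))
  out <- crossprod(R, z)
  rownames(out) <- meta$region_id
  out
}

#' Simulate a regions x conditions effect matrix with a planted shared map
#'
#' Column c is `loading_c * shared + noise_sd * eps_c` with `eps_c`
#' independent smooth maps at the same lengthscale, emulating per-condition
#' effect-size maps that share one common disease dimension. The planted map
#' is attached as attribute `planted_shared` for recovery tests.
#'
#' @param meta a [parcellation_meta()].
#' @param shared_map the planted shared [parcel_map()].
#' @param cfg a [sim_config()] supplying `shared_loadings`, `noise_sd`,
#'   `lengthscale` and the seed for the noise maps.
#' @return An [effect_matrix()] with attribute `planted_shared`.
#' @export
simulate_effect_matrix <- function(meta, shared_map, cfg = sim_config()) {
  stopifnot(inherits(shared_map, "parcel_map"))
  if (length(shared_map$values) != n_regions(meta)) stopf("shared map / meta mismatch")
  k <- length(cfg$shared_loadings)
  noise <- if (cfg$noise_sd > 0)
    simulate_smooth_maps(meta, cfg$lengthscale, child_seed(cfg$seed, 101L), n = k)
  else matrix(0, n_regions(meta), k)
  vals <- outer(shared_map$values, cfg$shared_loadings) + cfg$noise_sd * noise
  em <- effect_matrix(vals, meta, conditions = paste0("cond", seq_len(k)))
  attr(em, "planted_shared") <- shared_map$values
  em
}

#' Simulate unimodal depth-wise intensity profiles
#'
#' Each region's profile is `baseline + amplitude * exp(-(d - peak)^2 /
#' (2 * 0.15^2)) + noise` over `n_depths` even depth fractions in \[0, 1\]
#' (0 = pial, 1 = white). The Gaussian bump has fixed width 0.15 depth
#' fractions so the only free shape parameter per region is the peak
#' location. Planted peak depths are attached as attribute `planted_peak`.
#'
#' @param meta a [parcellation_meta()].
#' @param peak_depth_map [parcel_map()] of per-region peak depths in \[0, 1\].
#' @param amplitude_map [parcel_map()] of positive bump amplitudes.
#' @param n_depths number of sampling depths (>= 4).
#' @param seed integer seed for the additive noise.
#' @param noise_sd SD of the i.i.d. sampling noise (default 0.01).
#' @param baseline profile baseline intensity (default 1).
#' @return A [profile_set()] with attribute `planted_peak`.
#' @export
simulate_profiles <- function(meta, peak_depth_map, amplitude_map,
                              n_depths = 14L, seed = 1L,
                              noise_sd = 0.01, baseline = 1) {
  if (n_depths < 4L) stopf("need at least 4 sampling depths")
  pk <- peak_depth_map$values
  am <- amplitude_map$values
  if (any(pk < 0 | pk > 1)) stopf("peak depths must lie in [0, 1]")
  if (any(am < 0)) stopf("amplitudes must be nonnegative")
  d <- seq(0, 1, length.out = n_depths)
  bump <- exp(-(outer(pk, d, `-`))^2 / (2 * 0.15^2))
  intens <- baseline + am * bump
  if (noise_sd > 0)
    intens <- intens + with_seed(seed,
      matrix(stats::rnorm(length(intens), sd = noise_sd), nrow(intens), ncol(intens)))
  ps <- profile_set(intens, meta, depth_fractions = d, source = "synthetic")
  attr(ps, "planted_peak") <- pk
  ps
}

#' Simulate connectivity with a planted one-dimensional axis
#'
#' Entry (i, j) is a squared-exponential kernel of the axis difference,
#' `exp(-(a_i - a_j)^2 / (2 h^2))`, plus symmetric noise; unit diagonal,
#' clipped below at zero. The gradient pipeline should recover the axis
#' ordering from this matrix. The planted axis is attribute `planted_axis`.
#'
#' @param meta a [parcellation_meta()].
#' @param axis_map the planted axis as a [parcel_map()].
#' @param noise SD of the symmetric additive noise (default 0).
#' @param seed integer seed.
#' @param bandwidth kernel bandwidth `h`; defaults to the axis SD.
#' @return A [connectivity_matrix()] (`kind = "functional"`) with attribute
#'   `planted_axis`.
#' @export
simulate_connectivity <- function(meta, axis_map, noise = 0, seed = 1L,
                                  bandwidth = NULL) {
  a <- axis_map$values
  if (any(!is.finite(a))) stopf("axis map must be finite")
  h <- bandwidth %||% stats::sd(a)
  if (!is.finite(h) || h <= 0) h <- 1
  A <- exp(-(outer(a, a, `-`))^2 / (2 * h^2))
  if (noise > 0) {
    E <- with_seed(seed, matrix(stats::rnorm(length(A), sd = noise), nrow(A), ncol(A)))
    A <- A + (E + t(E)) / 2
  }
  diag(A) <- 1
  A[A < 0] <- 0
  cm <- connectivity_matrix(A, meta, kind = "functional")
  attr(cm, "planted_axis") <- a
  cm
}

#' Simulate a multiscale feature panel with known informative support
#'
#' Informative columns are `beta_j * target + noise` (i.i.d. Gaussian noise,
#' SD `cfg$feature_noise_sd`); the remaining columns are independent smooth
#' maps carrying no information about the target. Default feature names
#' mirror a multiscale panel: two connectome gradients, five profile
#' features, ten transmitter maps. Ground-truth support is attribute
#' `planted_support`.
#'
#' @param meta a [parcellation_meta()].
#' @param target the [parcel_map()] the informative features predict.
#' @param cfg a [sim_config()].
#' @return A [feature_panel()] with attribute `planted_support` (logical per
#'   column).
#' @export
simulate_feature_panel <- function(meta, target, cfg = sim_config()) {
  p <- cfg$n_features
  if (p < 1L) stopf("feature set must be non-empty")
  info <- cfg$informative_features
  if (length(info) && (min(info) < 1L || max(info) > p))
    stopf("informative feature indices out of range")
  nr <- n_regions(meta)
  vals <- simulate_smooth_maps(meta, cfg$lengthscale, child_seed(cfg$seed, 202L), n = p)
  noise <- with_seed(child_seed(cfg$seed, 203L),
                     matrix(stats::rnorm(nr * length(info), sd = cfg$feature_noise_sd),
                            nr, length(info)))
  for (k in seq_along(info))
    vals[, info[k]] <- cfg$effect_beta[k] * target$values + noise[, k]
  nm <- default_feature_names(p)
  prov <- rep("other", p)
  prov[grepl("^gradient", nm)] <- "gradient"
  prov[nm %in% c("mean", "sd", "skewness", "kurtosis")] <- "moment"
  prov[nm == "externopyramidization"] <- "externopyramidization"
  prov[grepl("^(D[12]|5HT|FDOPA|GABAa|DAT|NAT|SERT)", nm)] <- "transmitter"
  fp <- feature_panel(vals, meta, features = nm, provenance = prov)
  support <- rep(FALSE, p)
  support[info] <- TRUE
  attr(fp, "planted_support") <- support
  fp
}

default_feature_names <- function(p) {
  base <- c("gradient_mpc", "gradient_fc", "mean", "sd", "skewness", "kurtosis",
            "externopyramidization", "D1", "D2", "5HT1a", "5HT1b", "5HT2a",
            "FDOPA", "GABAa", "DAT", "NAT", "SERT")
  if (p <= length(base)) base[seq_len(p)]
  else c(base, sprintf("feature%02d", seq_len(p - length(base))))
}
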