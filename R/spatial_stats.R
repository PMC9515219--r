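quaternion_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  a <- q[1L]; b <- q[2L]; c <- q[3L]; d <- q[4L]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3L, 3L, byrow = TRUE)
}

#' Generate spin-test permutations
#'
#' Builds the null permutations of the spatial spin test at parcel level:
#' for each rotation a uniform (Haar) random 3-D rotation is drawn (via a
#' normalized Gaussian quaternion), applied to the left-hemisphere
#' centroids, and its mirror image through the sagittal (x = 0) plane is
#' applied to the right hemisphere so homotopy is preserved. Each rotated
#' centroid is then assigned the index of the nearest original centroid in
#' the same hemisphere; duplicated assignments are permitted, as is standard
#' for centroid-based spin schemes.
#'
#' @param meta a [parcellation_meta()] with at least 2 regions per
#'   hemisphere.
#' @param n_rotations number of rotations (default 1000).
#' @param seed integer seed.
#' @param rotations optional list of explicit 3 x 3 rotation matrices
#'   (overrides random draws; mainly for testing).
#' @return An object of class `spin_permutations` with fields `assignments`
#'   (n_rotations x regions integer matrix: column i holds the source region
#'   index whose value region i receives under each rotation),
#'   `n_rotations`, `seed`, `meta`.
#' @export
generate_spins <- function(meta, n_rotations = 1000L, seed = 1L, rotations = NULL) {
  nL <- sum(meta$hemisphere == "L")
  nR <- sum(meta$hemisphere == "R")
  if (nL < 2L || nR < 2L) stopf("spin test needs at least 2 regions per hemisphere")
  idxL <- which(meta$hemisphere == "L")
  idxR <- which(meta$hemisphere == "R")
  CL <- meta$centroid[idxL, , drop = FALSE]
  CR <- meta$centroid[idxR, , drop = FALSE]
  M <- diag(c(-1, 1, 1))
  if (is.null(rotations)) {
    rotations <- with_seed(seed, lapply(seq_len(n_rotations), function(i)
      quaternion_rotation(stats::rnorm(4L))))
  }
  n_rotations <- length(rotations)
  assign_tab <- matrix(NA_integer_, n_rotations, n_regions(meta))
  for (r in seq_len(n_rotations)) {
    RL <- rotations[[r]]
    RR <- M %*% RL %*% M
    rotL <- CL %*% t(RL)
    rotR <- CR %*% t(RR)
    # nearest original centroid = largest dot product on the unit sphere
    assign_tab[r, idxL] <- idxL[max.col(rotL %*% t(CL), ties.method = "first")]
    assign_tab[r, idxR] <- idxR[max.col(rotR %*% t(CR), ties.method = "first")]
  }
  structure(list(assignments = assign_tab, n_rotations = n_rotations,
                 seed = as.integer(seed), meta = meta),
            class = "spin_permutations")
}

#' Spin-test correlation between two parcel maps
#'
#' Pearson correlation of `map_a` and `map_b` with significance from the
#' spatial spin null: `map_a` (the target map, by fixed convention) is
#' permuted by each spin assignment and the two-tailed permutation p-value
#' is `(1 + #\{|r_null| >= |r_obs|\}) / (1 + n_rotations)`, which is bounded
#' away from zero at finite rotation counts.
#'
#' @param map_a,map_b aligned [parcel_map()]s (no masked values; `map_a` is
#'   the one permuted).
#' @param spins a [generate_spins()] result on the same parcellation.
#' @return A list of class `correlation_test` with `r_observed`, `p_spin`,
#'   `q_fdr` (NA until a family correction sets it), `null_distribution`.
#' @export
spin_correlation <- function(map_a, map_b, spins) {
  a <- map_a$values
  b <- map_b$values
  if (length(a) != length(b) || length(a) != ncol(spins$assignments))
    stopf("maps and spins must share one parcellation")
  if (any(!is.finite(a)) || any(!is.finite(b))) stopf("masked values; align first")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stopf("zero-variance map")
  r_obs <- stats::cor(a, b)
  perm <- matrix(a[t(spins$assignments)], nrow = length(a))  # regions x rotations
  null_r <- col_cor(b, perm)
  p <- (1 + sum(abs(null_r) >= abs(r_obs))) / (1 + spins$n_rotations)
  structure(list(r_observed = r_obs, p_spin = p, q_fdr = NA_real_,
                 null_distribution = null_r),
            class = "correlation_test")
}

#' @export
print.correlation_test <- function(x, ...) {
  cat(sprintf("r = %.3f, p_spin = %.4g%s\n", x$r_observed, x$p_spin,
              if (is.na(x$q_fdr)) "" else sprintf(", q_fdr = %.4g", x$q_fdr)))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment,
#' `q_(i) = min_{j >= i} (p_(j) * m / j)` clipped at 1, returned in input
#' order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length and order.
#' @export
fdr_correct <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Spin-test a target map against every feature of a panel
#'
#' One [spin_correlation()] per panel column, with Benjamini-Hochberg
#' q-values computed across the panel as a single family.
#'
#' @param target [parcel_map()] to correlate (and permute).
#' @param panel a [feature_panel()].
#' @param spins a [generate_spins()] result.
#' @return A data.frame with columns `feature`, `r`, `p_spin`, `q_fdr`, rows
#'   ordered as the panel; the rotations x features matrix of null
#'   correlations is attached as attribute `null_distributions`.
#' @export
test_feature_panel <- function(target, panel, spins) {
  tests <- lapply(seq_along(panel$features), function(j)
    spin_correlation(target, parcel_map(panel$values[, j], panel$meta,
                                        panel$features[j]), spins))
  p <- vapply(tests, `[[`, numeric(1L), "p_spin")
  out <- data.frame(feature = panel$features,
                    r = vapply(tests, `[[`, numeric(1L), "r_observed"),
                    p_spin = p,
                    q_fdr = fdr_correct(p))
  attr(out, "null_distributions") <-
    vapply(tests, `[[`, numeric(spins$n_rotations), "null_distribution")
  out
}

#' Rescale a map linearly to the 0-100 range
#'
#' Affine rescaling so the minimum maps to 0 and the maximum to 100, the
#' normalisation conventionally applied to PET tracer density maps before
#' spatial correlation (Pearson r is invariant to it).
#'
#' @param map a non-constant [parcel_map()].
#' @return A rescaled [parcel_map()].
#' @export
rescale_0_100 <- function(map) {
  v <- map$values
  rng <- range(v, na.rm = TRUE)
  if (diff(rng) == 0) stopf("cannot rescale a constant map")
  parcel_map(100 * (v - rng[1L]) / diff(rng), map$meta, name = map$name)
}

#' Stratify a map by community or hierarchy labels
#'
#' Per-class count, mean and SD of the map values — the radar-plot summary
#' of a map over functional communities or cortical hierarchy levels.
#' Classes with no regions are reported with count 0 and masked statistics.
#'
#' @param map a [parcel_map()].
#' @param label `"community"` or `"hierarchy"`.
#' @return A data.frame with columns `class`, `n`, `mean`, `sd`.
#' @export
stratify_map <- function(map, label = c("community", "hierarchy")) {
  label <- match.arg(label)
  f <- map$meta[[label]]
  v <- map$values
  lev <- levels(f)
  data.frame(class = lev,
             n = as.integer(table(f)[lev]),
             mean = vapply(lev, function(l)
               if (any(f == l)) mean(v[f == l]) else NA_real_, numeric(1L)),
             sd = vapply(lev, function(l)
               if (sum(f == l) > 1L) stats::sd(v[f == l]) else NA_real_, numeric(1L)),
             row.names = NULL)
}
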