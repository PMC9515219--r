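---
title: "Methods: shared disease dimensions and their multiscale context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shared disease dimensions and their multiscale context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Psychiatric and neurodevelopmental conditions show partially overlapping
patterns of cortical thickness alteration. Given one effect-size map per
condition on a common cortical parcellation (68 regions of a standard
whole-cortex anatomical atlas), `transgrad` asks three questions:

1. Is there a *shared disease dimension* — a single spatial axis of
   susceptibility common to the conditions?
2. Where does that axis sit relative to the cortex's own organisational
   axes — connectome gradients, laminar/cytoarchitectonic differentiation,
   and neurotransmitter system distributions?
3. Can the axis be predicted from those multiscale features, and which
   features carry the prediction?

Every stage is exercised on synthetic data with planted, recoverable
structure, so the statistical machinery is validated end to end without any
external download.

# The shared dimension

The effect matrix `X` (regions × conditions) is decomposed by PCA; the first
component's region scores are the shared dimension. Two centering/scaling
conventions are exposed because the variance-explained figure depends on the
choice and published analyses rarely state it:

* `scaling_mode = "center"` (default): column (condition) means removed,
  variances untouched. Conditions with larger overall effects weigh more.
* `scaling_mode = "zscore"`: conditions additionally scaled to unit
  variance.

Eigenvector signs are arbitrary, so a fixed orientation rule is applied:
every component is flipped, if necessary, so that its correlation with the
row-mean (mean-effect) map is positive. Regions with the most negative mean
effect — the strongest atrophy — therefore receive negative scores, which
matches the display convention of cross-disorder analyses. A component
orthogonal to the mean map (|r| < 1e-12) falls back to making its
largest-magnitude loading positive.

Sensitivity is assessed by leave-one-condition-out refits; similarity to the
all-conditions solution is reported as |r| because refitting can flip the
eigenvector. The mean-effect map is computed alongside as a model-free
companion. Components beyond the first are computed and reported, but every
default downstream consumer takes component 1.

# Spatial permutation (spin) testing

Correlations between cortical maps are inflated by spatial autocorrelation;
naive parametric p-values are anticonservative. The spin test preserves each
map's spatial structure under the null by rotating one map over the sphere:

* one Haar-uniform 3-D rotation per permutation (normalised Gaussian
  quaternion);
* the rotation applies to left-hemisphere centroids and its mirror image
  through the sagittal plane to the right hemisphere, preserving homotopy;
* each rotated centroid takes the value of the nearest original centroid in
  the same hemisphere; duplicate assignments are accepted, as is standard
  for centroid-level (as opposed to vertex-level) spin schemes.

Conventions that had to be pinned because they change p-values slightly:
the *target* map (`map_a`) is the one permuted, and the two-tailed p-value
uses the +1-corrected counting rule `p = (1 + #{|r_null| >= |r_obs|}) /
(1 + n_rotations)`, which keeps p strictly positive and the test valid at
finite rotation counts. Family-wise control across a feature panel uses
Benjamini–Hochberg FDR (`stats::p.adjust`, verified in the tests against a
min-over-suffix brute force).

The headline property is calibration: for independent but spatially smooth
map pairs the empirical type-I error at α = 0.05 stays within Monte-Carlo
bounds of the nominal level, and for i.i.d. maps the p-value distribution is
uniform. Both are checked by the acceptance suite at 500 map pairs × 1000
rotations.

# Profile features

Depth-wise intensity profiles (pial = depth 0, white = depth 1) summarise
laminar structure. Per region we compute the arithmetic mean, sample SD
(n − 1), moment skewness `g1 = m3/m2^1.5` and excess kurtosis
`g2 = m4/m2^2 − 3` with n-denominator central moments — the population-
moment estimators that are the default of the common scientific stacks, not
the bias-corrected variants; constant profiles get skewness = kurtosis = 0
with a warning rather than NaN.

Externopyramidization condenses a profile into one laminar-shift index:

```
EP = (peak intensity / mean intensity) * (1 - d_peak)
```

with `d_peak` the depth fraction of the profile maximum. The second factor
is `1 − thickness_supra/thickness_total` (the supragranular share of
thickness above the peak); a formulation that subtracts the supragranular
thickness before dividing is dimensionally inconsistent and is not used.
Two micro-conventions are fixed: "intensity" in the numerator is the *peak*
intensity (the ratio is otherwise undefined for a whole profile), and ties
at the maximum resolve to the shallowest depth, so a uniform profile gets
EP = 1 exactly. EP is invariant to positive rescaling of a profile and
non-increasing as a bump of fixed shape is translated deeper — both are
tested properties.

# Similarity matrices and gradients

**Microstructural profile covariance (MPC)** is the pairwise partial
correlation of region profiles controlling for the cortex-average profile,
computed by the first-order partial-correlation identity and verified
against an explicit regression-residual oracle. Negative entries are set to
zero; surviving entries r are mapped by `log(r/(1−r))` with r clipped at
1 − 1e-9. The literature says only "log-transformed"; the logit form is used
here because it is monotone, maps (0,1) onto the real line, and every
downstream result depends only on monotone structure. It is isolated behind
`build_mpc` so it can be swapped.

**Functional connectivity** enters as a correlation matrix; `fisher_z_matrix`
applies the variance-stabilising arctanh with ±(1 − 1e-9) clipping.

**Gradients** follow the standard connectome-gradient recipe: keep the top
10% entries per row (ties to the lower column index; the result is
intentionally left asymmetric because the subsequent kernel compares rows),
build the normalized-angle affinity `1 − arccos(cos sim)/π`, and
eigendecompose the density-normalised diffusion operator
(`alpha = 0.5`, `t = 0`). With `t = 0` component k is scaled by
`λ_k/(1−λ_k)` — the automatic-diffusion-time convention without which the
`(α, t) = (0.5, 0)` parameter pair would be meaningless. The eigenproblem is
solved densely through the symmetric conjugate operator; parcel counts in
this setting are at most a few hundred, so no iterative solver is needed.
Components are sign-oriented by positive correlation with the first
centroid coordinate, an arbitrary but fixed convention.

# Nested LASSO prediction

The shared dimension is predicted from the multiscale panel with 5-fold
nested cross-validation, repeated (default 100 times) over fresh fold
assignments. Design choices the literature leaves open, pinned here:

* penalty grid: 100 log-spaced values from the data-derived maximal penalty
  `max|X'y|/n` down to 1e-4 of it, recomputed per outer training set;
* inner selection by lowest mean inner-CV MAE, ties to the larger penalty;
* features standardized with training-fold statistics only (inner fits use
  inner-training statistics) — LASSO is scale-sensitive and the panel mixes
  units; the intercept is never penalized;
* selection frequency counts a nonzero coefficient in the outer-fold refit.

The permutation test shuffles the target across regions and reruns the
nested procedure; each shuffle uses `reduced_repeats = 1` because the null
*location* is insensitive to the repeat count, while the observed statistic
keeps the full repeat count. A known property worth stating: under a null
target the out-of-fold correlation is not centered at zero but slightly
*below* it (≈ −1/(k−1) when models collapse to fold-wise intercepts, since a
fold's training mean anti-correlates with its held-out mean). The
permutation null carries the same bias, so the test stays calibrated; the
leakage check in the tests is accordingly one-sided (no *positive* bias).

# The synthetic cohort

The generator plants exactly the structure each stage is supposed to find:

* **Parcellation**: 34 regions per hemisphere on a golden-angle spiral,
  mirror-symmetric hemispheres, 7 community and 4 hierarchy labels from
  fixed anchor directions. Deterministic — no seed involved.
* **Smooth maps**: Gaussian-process draws with squared-exponential kernel of
  great-circle distance, lengthscale 0.6 rad, 1e-8 jitter. That kernel is
  positive definite on the sphere only up to moderate lengthscales (at 68
  regions it loses definiteness above ≈ 0.7 rad), and the generator errors
  rather than silently repairing an indefinite covariance.
* **Effect matrices**: loadings (1, 1, 1, 0.8, 0.8, 0.6) on one shared map
  plus condition-specific smooth noise, default SD 0.88 so the shared
  component carries ≈ half of the total variance — deliberately a hard
  regime. The best linear recovery of the planted map then has
  r = sqrt(Σl²/(Σl² + σ²)) ≈ 0.93, a ceiling worth keeping in mind when
  reading recovery numbers.
* **Profiles**: baseline 1 + Gaussian bump of width 0.15 depth fractions at
  a planted peak depth; one free location parameter keeps recovery tests
  interpretable.
* **Connectivity**: squared-exponential kernel of planted-axis differences;
  the embedding recovers the axis ordering essentially perfectly when the
  matrix is embedded directly; row-sparsifying 68 regions to 7 surviving
  neighbours first costs accuracy, which is a parcel-count effect, not an
  estimator property.
* **Feature panels**: 17 columns named after a multiscale panel (two
  gradients, five profile features, ten transmitter maps), of which three
  are informative with coefficient 1 and i.i.d. noise of SD √3, putting the
  best-case R² near 0.5. The remaining columns are independent smooth maps.

What the generator does **not** emulate: realistic cortical geometry and
region shapes, inter-subject variability, distance-dependent connectivity
artifacts, non-stationary autocorrelation, and correlated "noise" features.
That last point matters: independent smooth maps on 68 regions at
lengthscale 0.6 have so few effective degrees of freedom that their chance
correlation with an equally smooth target routinely reaches |r| ≈ 0.5–0.7,
as large as a planted signal at R² = 0.5. Feature-selection results at this
parcel resolution therefore say which features predict *this cortex's*
pattern, not which ones are causally informative — precisely why the spin
test, not the selection frequency, is the inferential instrument for
map-to-map association. Passing recovery tests on this cohort demonstrates
correctness of the machinery, not performance on real data.

# Problem sizes and runtimes

The test suite and the acceptance script run everything at the reference
study scale: 68 regions, 6 conditions, 14 depths, 1000 spin rotations, 500
calibration map pairs, 100 prediction repeats, and 200–500 permutation
shuffles; the embedding oracle uses 100 random 20-node affinities. These
sizes were chosen so the whole validation cycle completes in a few minutes
on a single core while keeping every Monte-Carlo bound meaningful.

# Known limitations

* Hemisphere handling after region exclusion is by intersection
  (`align_sources`); no reweighting is attempted.
* The MPC log transform and the PCA scaling mode are conventions, not
  identities; both are isolated and documented so alternates can be swapped.
* Parcel-level spins with nearest-centroid reassignment duplicate some
  regions per rotation; variogram-matching nulls are out of scope.
* The 10% row-density default is tuned to connectome matrices with hundreds
  of parcels; at 68 regions it is aggressive, and gradient fidelity improves
  markedly at higher densities.
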