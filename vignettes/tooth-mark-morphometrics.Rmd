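---
title: "Comparing carnivore tooth-mark morphologies: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing carnivore tooth-mark morphologies: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothmarks)
```

## The problem

Carnivores feeding on bone leave two kinds of diagnostic traces: *tooth
pits* (cusp depressions) and *tooth scores* (elongated drag marks).
Taphonomists use the geometry of these marks to identify the animal
responsible and to reason about its behaviour.  This package implements
a complete statistical workflow for asking whether mark morphology
differs between groups of animals — captive versus wild wolves, or
separate populations — from landmark data:

* tooth scores enter as 7-landmark 2D cross-sections (shoulders LM1 and
  LM7, deepest point LM4, computed wall landmarks LM2/LM3 and LM5/LM6),
  from which seven measurements are derived: three widths (WIS, WIM,
  WIB), the depth D, the two wall lengths LDC and RDC, and the opening
  angle OA;
* tooth pits enter as 30-landmark 3D configurations (5 fixed landmarks
  defining the length axis, width axis and deepest point, plus a 5 x 5
  surface patch).

Because no raw data ship with the package, a synthetic-data generator
(`simulate_scores()`, `simulate_pits()`, `paper_default_specs()`)
produces datasets with the statistical structure the analysis assumes,
so every stage is testable end to end.

## Statistical models and conventions

### Opening angles are circular data

OA is an angle, so ordinary moments are replaced by circular
statistics (`circ_descriptives()`): the mean direction and the mean
resultant length `Rbar`, sample circular variance `v = 1 - Rbar`, and
standardised skewness and kurtosis computed from the second
trigonometric moment about the mean direction.  Angles are radians
internally and degrees at every interface.  The circular median for an
even sample size is the midpoint direction of the two central order
statistics, with ties broken towards the mean direction.

Uniformity is checked with the Rayleigh test (large-sample series
p-value) and reflective symmetry with a z-type test on the
standardised second *sine* moment about the median.  Two samples are
compared three ways (`circ_two_sample()`): a bootstrap Watson-type
test of common mean direction (statistic `Y_g`), Fisher's
randomization test of common median (`P_g`), and the randomization
Mardia–Watson–Wheeler uniform-scores test (`W_g`).  Resampling
p-values use the add-one estimator `(exceedances + 1) / (reps + 1)` so
they can never be exactly zero; the default is 9999 replicates, and
every randomized routine takes an explicit seed and restores the
caller's RNG state.

No dedicated Von-Mises goodness-of-fit test is implemented: uniformity
plus reflective symmetry act as the gate for treating a sample as
Von-Mises-like, which mirrors how the workflow decides between the
mean and the median as the central tendency (the robust branch is
taken when the symmetry test's calibrated null probability falls below
the 0.003 evidence threshold; both statistics are always reported,
with the robust one flagged).

### Robust univariate statistics

Linear measurements are right-skewed, so a Shapiro–Wilk gate decides
per variable between a classical branch (mean, SD) and a robust branch
(median, square root of the biweight midvariance with tuning constant
9 on MAD-standardised deviations).  The gate threshold is 0.003 — the
two-sided tail mass outside three standard deviations of a Gaussian —
rather than 0.05, consistent with the evidence threshold used
everywhere else in the pipeline.

Group similarity is assessed by equivalence testing (`tost()`): two
one-sided tests whose *null* is a difference of at least `epsilon`
standardised units, so small p-values are evidence that groups are
equivalent.  The parametric branch uses Welch's statistic; the robust
branch (rTOST) uses Yuen's trimmed statistic with 20% trimming and
winsorized variances.  The equivalence bound is expressed in Cohen's d
units against the method's own pooled scale (ordinary or winsorized
pooled SD) with a default of 0.2; it is configurable and recorded in
every result row, since conclusions scale with it.  Multivariate
equivalence operates on the principal components retained to 95% of
variance and aggregates as the PC-wise maximum p and the summed |d| —
an explicit package convention.

A note on power: with the combined TOST statistic, declaring
equivalence at `epsilon = 0.2` requires several hundred observations
per group; below that the test is conservative (it withholds an
equivalence claim), which is the safe direction for a morphological
comparison.

### Evidence calibration instead of significance

No output of this package uses the word "significant", and no decision
rests on `p < 0.05`.  Every p-value is accompanied by three calibrated
quantities built on the kernel `x(p) = -e p log(p)`:

* `bfb(p) = 1/x(p)` for `p <= 1/e`, saturating at 1 above it — the
  upper bound on the Bayes factor in favour of the alternative;
* `fpr(p, prior)` — the posterior probability that a claimed effect is
  absent, given prior probability `prior` that it is real (default
  0.5, i.e. prior odds 1);
* `p_h0(p)` — a continuous posterior null probability equal to
  `x/(1+x)` below the branch point `p* = 0.3681` (the calibration
  curve's point of maximum curvature, numerically 1/e) and `1/(1+x)`
  above it, rising from 0 through 0.5 at `p*` to 1.

The lower branch of `p_h0` coincides with the FPR at prior 0.5; the
upper branch mirrors it so that large p-values express genuine support
for the null.  Strong evidence is declared below `p(H0) = 0.003`.
These closed forms were validated against more than twenty published
calibration pairs to printed precision before being wired into the
pipeline (the package's calibration tests keep that table frozen).

### Geometric morphometrics

`gpa()` performs Generalized Procrustes Analysis: translation to a
common centroid, optional scaling to unit centroid size, and iterative
rotation to the evolving mean until the mean shape changes by less
than `1e-8` (at most 100 iterations), followed by orthogonal
projection onto the tangent space at the mean.  Reflections are never
allowed during superimposition: digitised marks have consistent
handedness.  `scale = TRUE` gives shape space; `scale = FALSE` retains
size (form space).  Allometric regression (`allometry_test()`) always
runs in shape space — tangent coordinates regressed on log centroid
size (or another covariate, such as the captivity-stress proxy) with a
Goodall-type F from summed squared Procrustes residuals and a
residual-randomization permutation p-value (999 permutations by
default, seeded).  Form space is a *downstream* choice: when the
calibrated null probability of the allometry test falls below 0.25,
subsequent PCA and equivalence testing run on form-space coordinates;
otherwise on shape space.  The 0.25 convention sits deliberately
between the "fairly strong tendency" and the "inconclusive" regimes of
the calibrated scale; it is a package convention, recorded in the run
manifest.

The stress covariate (`stress_covariate()`) is a per-park scalar:
number of individuals divided by enclosure area, defaulting to 7/2700
and 5/10000 individuals per square metre for the two captive parks of
the study conditions and 0 for wild populations.  The construction is
one of several defensible readings of "individuals in the space
provided" and is therefore exposed as a configurable table.

`tps_grid()` computes 2D thin-plate-spline deformation grids with
kernel `U(r) = r^2 log(r^2)`; the affine part absorbs rigid and shear
components, so bending energy is exactly zero for affine deformations.
`tsne_embed()` is an exact (non-Barnes-Hut) t-SNE into three
dimensions: random initialisation under a seed, 500 iterations,
perplexity `ceiling(sqrt(n))`, early exaggeration for the first 100
iterations and momentum switching at 250 — appropriate at the sample
sizes involved (hundreds of specimens), where the exact gradient is
cheap and deterministic given the seed.

### Bayesian effect sizes

`fit_two_group()` fits independent Student-t likelihoods to two
samples: per-group location, scale and normality parameters with
weakly informative, data-scaled priors (normal locations with SD
`sqrt(1000)` times the pooled SD, half-normal scales at ten times the
pooled SD, degrees of freedom `1 + Exponential(29)`).  Sampling is
Gibbs/slice MCMC via JAGS with 4 chains, 1000 adaptation/burn-in and
5000 draws per chain by default.  Reported are the posterior mean of
Cohen's delta (location difference over the pooled posterior scale),
the 95% highest-density interval of the raw location difference, and
the Probability of Superiority computed from posterior-predictive
draws.  Convergence is checked with R-hat on every parameter (flagged,
never silently ignored, above 1.01) and effective sample sizes;
divergent transitions do not exist for this sampler, so the
diagnostics report zero divergences by construction.  The normality
parameter mixes slowest, and with short chains the 1.01 flag is
deliberately conservative.  A `target_accept` argument exists purely
for interface compatibility with gradient-based samplers.

## What the synthetic data emulate — and what they do not

`paper_default_specs()` encodes the study conditions: four populations
with tooth-score sample sizes 56/113/63/56 (pits 42/113/49/79),
opening-angle central directions 158.67/147.09/132.51/132.19 degrees
with concentrations back-solved from circular variances
0.02/0.02/0.03/0.01, WIS medians 0.54/0.48/0.47/0.56 mm and depth
medians 0.05/0.07/0.09/0.12 mm with the published robust deviations.
Lognormal marginals are used because the measurements are non-negative
and right-skewed, with the median as the central parameter; depth and
width are coupled by a Gaussian copula whose correlation
`sin(pi tau / 2)` targets the published depth-width association
`tau = 0.59`.  Pit dimensions (length median 2.0 mm, depth median
0.35 mm) are generic wolf-pit scales — the published tables do not
constrain them — and default pits carry no group effect and no
allometric slope, matching the study's conclusion for pits.

Each synthetic score is geometrically consistent: shoulders span the
drawn WIS, the base sits at the drawn depth, and its lateral position
is solved so the interior angle equals the drawn OA, with the side of
the asymmetry randomised.  Two consequences deserve emphasis:

* *Feasibility truncation.*  A triangle with width `w` and depth `d`
  admits no opening angle above `2 atan(w / 2d)`, and the published
  group centres sit almost exactly at that bound — real marks are
  near-symmetric V-shapes.  Infeasible angles are redrawn given the
  (WIS, D) pair (so the metric marginals are preserved), which
  truncates the upper OA tail: realised central angles come out a few
  degrees below the nominal Von Mises means (about 141 degrees rather
  than 151 for pooled captive scores).  The captive-wild ordering and
  separation, which is what the downstream tests consume, is
  unaffected.
* *Straight walls.*  Synthetic profiles have straight walls, so
  WIM = (2/3) WIS and WIB = (1/3) WIS hold exactly and the three width
  variables are perfectly collinear.  Real cross-sections have curved
  walls; passing tests on synthetic data therefore validate the
  machinery, not the empirical distinctness of the width variables.

The pit generator produces elliptic-paraboloid depressions sampled on
a regular 5 x 5 grid with isotropic landmark jitter (SD 1% of pit
length).  An optional allometric displacement field
(`pit_allometry_direction()`) shifts shape linearly with centred log
centroid size; the field touches only the 25 patch landmarks, because
displacing the five fixed landmarks would interact with the
orientation rules (length arm longer than width arm, LM1 the farther
endpoint) that the generator re-establishes by relabelling, scrambling
the planted signal exactly for the extreme sizes that carry most of
it.  Only the component of the field orthogonal to translation,
rotation and scaling is recoverable after superimposition — the
similarity group is quotiented out — which the recovery tests respect.

## Numerical choices and degenerate inputs

* Computed wall landmarks are placed at equal *arc length* (1/3 and
  2/3) along each wall polyline, matching curve-tracing digitisers and
  independent of the coordinate frame; degenerate zero-length walls
  are errors.
* Depth is the absolute perpendicular distance from LM4 to the
  LM1-LM7 chord, so profiles may enter translated, rotated or
  reflected; all seven measurements are rigid-motion invariant and
  lengths scale linearly under uniform scaling.
* Flat profiles give D = 0 and OA = 180 degrees; coincident shoulders
  are an error.
* `bfb()`, `fpr()` and `p_h0()` require p strictly inside (0, 1);
  pipeline callers clamp boundary values produced by rounding.
* Permutation and bootstrap p-values are bit-reproducible under a
  fixed seed; across seeds they vary within binomial error of the
  replicate count.
* The morphologika reader is case-insensitive, skips unknown blocks
  with a warning, and fails with the offending line on count
  mismatches or non-numeric coordinates.

## Problem sizes used by the validation suite

The package's own checks run at deliberately modest sizes chosen to
give stable empirical rates: type-I calibration of the randomization
tests uses 500 null replicates with 199 resamples at 30-40 specimens
per group; Bayesian recovery uses 20 replicates of n = 150 with two
shortened chains; the end-to-end run uses the full study-condition
sample sizes with 999 resampling replicates.  The analysis scripts
under `analysis/` run the full-size configuration (9999 replicates)
and write their tables under `results/`.

## Known limitations

* Cross-section extraction from 3D surface models is out of scope;
  profiles enter as polylines or finished landmark configurations.
* The synthetic generator does not emulate curved score walls,
  mark-frequency data, or surface micro-topography.
* Axial (180-degree periodic) angular data and Von Mises mixtures are
  not supported.
* Multivariate equivalence is PC-wise, not a joint Hotelling-type
  test; the aggregation convention (max p, summed |d|) is simple and
  conservative.
* Published interval estimates for the Bayesian location differences
  are internally inconsistent in the source tables (intervals
  narrower than the reported differences); they are not used as
  validation anchors anywhere in this package.
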