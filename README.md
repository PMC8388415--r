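# toothmarks

Landmark-based geometric morphometrics and calibrated statistics for
carnivore tooth marks on bone.

Taphonomists and ecologists compare the shapes of *tooth scores*
(elongated drag marks, analysed through 7-landmark 2D cross-sections)
and *tooth pits* (cusp depressions, 30-landmark 3D configurations) to
ask whether different animals — or the same animals under different
conditions, such as captivity — leave measurably different marks.
This package provides that workflow end to end for R users working
with morphologika or TPS landmark files:

* **Measurements.** From a 7-landmark cross-section: the widths
  WIS = |LM1−LM7|, WIM = |LM2−LM6|, WIB = |LM3−LM5|, the wall lengths
  LDC and RDC, the depth D (perpendicular distance from LM4 to the
  LM1–LM7 chord) and the opening angle OA (interior angle at LM4).
  Computed wall landmarks are placed at equal arc length along each
  wall.
* **Circular statistics** for opening angles: mean/median direction,
  circular variance v = 1 − R̄, standardised skew and kurtosis,
  Rayleigh uniformity, a reflective-symmetry test, and three
  seeded randomization two-sample tests (bootstrap Watson Y_g,
  Fisher median P_g, Mardia–Watson–Wheeler W_g).
* **Robust univariate statistics**: Shapiro–Wilk gating at the 0.003
  threshold, median / √BWMV descriptives, equivalence testing (TOST
  with Welch's t; rTOST with Yuen's trimmed t), Pearson and Kendall
  correlations.
* **Geometric morphometrics**: Generalized Procrustes Analysis in
  shape or form space with tangent projection, shape PCA, permutation
  tests for allometry (Goodall-type F on log centroid size or a
  captivity-stress covariate), thin-plate-spline deformation grids,
  and exact 3D t-SNE embeddings (perplexity ⌈√n⌉, 500 iterations).
* **Bayesian effect sizes**: robust two-group Student-t models by
  MCMC, reporting Cohen's δ, the 95% HDI of the difference and the
  Probability of Superiority, with R-hat/ESS diagnostics.
* **Evidence calibration.** Every p-value is mapped through
  x(p) = −e·p·ln p to the Bayes Factor Bound BFB = 1/x, the False
  Positive Risk FPR = 1/(1 + BFB·prior odds), and a continuous
  posterior null probability p(H₀) = x/(1+x) for p ≤ 0.3681 and
  1/(1+x) above; evidence statements use the p(H₀) scale with a
  0.003 threshold, never the word "significant".
* **Synthetic data.** A generator that emulates wolf tooth-mark
  samples (lognormal width/depth marginals coupled by a Gaussian
  copula targeting Kendall's τ = 0.59, Von Mises opening angles,
  geometrically consistent profiles, elliptic-paraboloid pits with an
  optional planted allometric slope), so the whole pipeline is
  testable without any external data.

## Worked example

```r
library(toothmarks)

# p-value calibration
round(as.numeric(bfb(0.01)), 2)      # 7.99   (odds at most for Ha)
round(100 * fpr(0.01, 0.3), 1)       # 22.6   (% false-positive risk)
round(100 * p_h0(0.082), 1)          # 35.8   (% posterior null prob.)

# simulate the four study populations and compare opening angles
specs <- paper_default_specs(seed = 20260930)
scores <- simulate_groups(specs$scores, "scores")
m <- score_metrics_table(scores)
circ_two_sample(m$OA[m$captivity == "captive"],
                m$OA[m$captivity == "wild"],
                "mww_distribution", reps = 9999, seed = 1)
#   statistic      p           method reps
#        61.7  1e-04 mww_distribution 9999
```

The full analysis lives in `analysis/01_simulate.R` through
`analysis/05_full_pipeline.R`; each script prints what it finds and
writes its tables under `results/`.  On the default configuration the
headline pattern is:

```
captive: median WIS 0.50 mm, median D 0.06 mm, median OA 140.3 deg (n = 169)
wild:    median WIS 0.49 mm, median D 0.09 mm, median OA 124.5 deg (n = 119)

captive vs wild opening angles:
           method statistic     p   p_h0
      watson_mean     153.2 1e-04 0.0025
    fisher_median      76.3 1e-04 0.0025
 mww_distribution      61.7 1e-04 0.0025

captive vs wild equivalence (rTOST, d-units):
 variable     d     p  p_h0
      WIS 0.343 0.775 0.651
        D 1.031 1.000 1.000
```

Read: captive and wild opening angles differ on all three circular
tests (p(H₀) = 0.25%); score *depth* is the discordant measurement —
its equivalence null probability (100%) far exceeds the width
variables' — while widths are near-identical between groups.  Pits,
analysed the same way, show no captive/wild separation.

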