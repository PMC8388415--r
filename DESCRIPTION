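Package: toothmarks
Title: Geometric Morphometrics and Calibrated Statistics for Carnivore Tooth Marks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based analysis of carnivore tooth-mark morphology.
    Reads and writes morphologika and TPS landmark files, derives the seven
    standard tooth-score cross-section measurements from 7-landmark profiles,
    and provides the statistical machinery to compare mark morphologies
    between groups of animals: circular statistics for opening angles
    (Von Mises descriptives, Rayleigh uniformity, reflective symmetry, and
    three randomization two-sample tests), robust univariate statistics
    (biweight midvariance, Welch and Yuen equivalence tests), Generalized
    Procrustes Analysis in shape and form space with permutation tests for
    allometry, thin-plate-spline deformation grids, t-SNE embeddings, robust
    Bayesian two-group effect sizes, and a p-value calibration layer mapping
    p-values to Bayes factor bounds, false positive risks, and posterior
    null probabilities.  A synthetic-data generator emulates wolf tooth-mark
    samples so the full pipeline can be exercised and validated without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    coda,
    jsonlite,
    rjags,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
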