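Package: tripletdim
Title: Dimensionality Estimation for Psychophysical Scales from Triplet
    Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the number of perceptual dimensions underlying
    triplet similarity judgments ("is stimulus B or C more similar to A?").
    Scales are fitted by soft ordinal embedding (squared-hinge stress
    minimized with BFGS and random restarts), their fit is measured by
    cross-validated triplet accuracy under r-repeated k-fold
    cross-validation, and neighboring dimensions are compared with a
    variance-corrected one-sided paired t-test under Holm-Bonferroni
    step-down correction; the selected dimension is the lowest one beyond
    which test accuracy does not improve significantly. Includes a
    synthetic-observer simulator (normal ground-truth scales, Gaussian
    judgment noise rescaled to the spread of pairwise distances,
    lambda-scaled trial budgets, noise-ceiling estimation) so the whole
    pipeline can be validated without behavioral data, plus data-quality
    diagnostics and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
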