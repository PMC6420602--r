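Package: vfprog
Title: Detecting Glaucomatous Visual-Field Progression with Spatiotemporal
    Boundary Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting glaucomatous visual-field progression from
    longitudinal standard automated perimetry series on the 24-2 test
    pattern. Implements a Bayesian spatiotemporal boundary-detection model
    (an anatomically weighted conditional autoregressive field fitted by
    Metropolis-within-Gibbs MCMC) whose visit-to-visit variability in the
    spatial-correlation parameter, summarised per posterior draw by its
    coefficient of variation, yields the STBound predictor triple; the
    competing trend-based progression metrics (global-index regression,
    pointwise linear regression order statistics, mean slope, permutation of
    pointwise linear regression); a diagnostic-evaluation framework based on
    logistic combiners, AIC, full and partial AUC over the clinically
    relevant specificity band, and sensitivity-maximising thresholds at a
    specificity floor; longitudinal early-detection and time-to-first-
    diagnosis analyses on time-truncated series; and a synthetic
    visual-field cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    pROC
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
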