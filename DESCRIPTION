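Package: spautolog
Title: Auto-Logistic Spatial Modelling of Binary Health Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatial analysis of geocoded patient-level binary
    outcomes, built around the auto-logistic (autologistic) regression model:
    inverse-distance distance-band spatial weights, the normalized
    autocovariate of neighbouring outcomes, global and local Moran's I with
    permutation inference, logistic and auto-logistic model fitting with odds
    ratios and pseudolikelihood standard errors, two-stage variable selection,
    AIC/AUC model comparison, residual spatial-autocorrelation diagnostics,
    a Gibbs-sampled synthetic geocoded cohort generator, and an end-to-end
    analysis pipeline with CSV/GeoJSON exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    geosphere,
    mgcv,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
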