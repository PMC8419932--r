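Package: swdglmm
Title: Power and Sample Size for Stepped-Wedge Trials Under Generalized
    Linear Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytic power and sample-size calculation for cross-sectional
    stepped-wedge cluster-randomized trials with normal, binary, or count
    outcomes modelled on their natural link scale (identity, logit, log)
    under generalized linear mixed models.  The covariance of the estimated
    intervention effect is obtained from the penalized quasi-likelihood /
    Laplace approximation with the random effects plugged in at their prior
    mode of zero, accumulated cluster by cluster and inverted efficiently
    via exchangeable-row aggregation and the Woodbury matrix identity, so
    that designs with two levels of clustering and hundreds of clusters are
    evaluated in milliseconds.  Includes integer solvers for the smallest
    cluster-period size or number of clusters reaching a power target,
    power curves, built-in trial presets, and a Monte-Carlo validation
    harness with an internal maximum-likelihood GLMM fitter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
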