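Package: emels
Title: Extended Mixed-Effect Location-Scale Models for Forecasting Intensive
    Longitudinal Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits longitudinal mixed-effect location-scale models in which
    every person has their own mean level, log residual variance, and
    (atanh) lag-1 autocorrelation, all treated as correlated normal random
    effects over an AR(1) residual process.  Estimation is by marginal
    maximum likelihood with adaptive Gauss-Hermite quadrature.  The package
    also provides the L1-penalised (Lasso) variant with block coordinate
    descent over a penalty path, a regression-tree variant that alternates
    between CART on random-effect-freed residuals and the location-scale
    model on leaf-membership dummies, empirical-Bayes random-effect
    prediction, H-step forecasting for trained persons, new persons without
    history and new persons with history, forecast-error variances, and
    seed-deterministic generators for ecological momentary assessment style
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
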