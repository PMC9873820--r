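Package: ampmilk
Title: Daily Milk Yield Estimation from Single AM or PM Milkings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates total daily milk yield of dairy cows from a single
    morning (AM) or evening (PM) milking, as used in AM-PM milk-recording
    plans. Implements the classical additive correction factor (ACF) and
    multiplicative correction factor (MCF) families indexed by milking
    interval class, linear regression estimators with continuous or
    discretized milking interval, and an exponential (log-linear ratio)
    regression model with a second-order Taylor moment correction for
    class-wise factors. Includes a truncated-normal herd simulator built on
    a saturating Michaelis-Menten yield curve, repeated k-fold
    cross-validation with a bias-variance decomposition of mean squared
    error and predictive R-squared accuracy, and analysis of the
    discretization bias introduced by interval classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
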