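Package: jointpwr
Title: Power and Sample Size for the Joint Test of Intercept and Slope
    with Random Predictors
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact and approximate power and sample-size calculation for the
    joint F test that the intercept and slope coefficients of a linear
    regression equal hypothesized values, as used to validate a published
    regression formula against new data. Predictors are treated as random:
    the exact unconditional power averages the conditional noncentral-F
    power over the normal-theory distribution of the predictor mean and
    scatter, evaluated through a noncentral chi-square mixture. The
    mean-substitution approximation, conditional (fixed-design) power,
    asymptotic effect sizes, a minimal-sample-size search, and a Monte
    Carlo engine that validates the analytic power functions by simulation
    under normal and four standardized non-normal predictor families are
    included, together with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
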