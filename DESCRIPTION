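Package: gma
Title: Generalized Model Aggregation of Published Statistical Findings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the parameters of a user-declared data-generating
    meta-model by simulating the statistical procedures of previously
    published studies and matching the simulated summary statistics
    ("signatures": regression coefficients, mean squared errors, R-squared,
    ANOVA mean squares, effect sizes, between-study variances) against the
    published ones. Provides the simulated-moments style estimator with an
    iteratively refined optimal weight matrix, asymptotic and parametric
    bootstrap confidence intervals, a chi-square goodness-of-fit statistic,
    a model selection criterion, leave-one-study-out outlier diagnostics,
    covariate samplers calibrated to reported moments, a measurement-error
    extension, and a suite of synthetic validation scenarios including a
    comparison against DerSimonian-Laird random-effects meta-analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
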