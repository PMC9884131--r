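Package: obreg
Title: Optimism-Bias Regularization for Regression Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: One-sided convex penalties that control the number of
    over- or under-predicted instances in regression models. Provides
    penalized linear regression and primal epsilon-insensitive support
    vector regression with the optimism-bias term, asymmetric error
    metrics (mean squared positive/negative error, side rates), a
    bias-variance simulation harness on replicated synthetic datasets,
    seeded generators for linear, epidemic-surge and degradation data,
    a sliding-window forecaster for count time series, and a
    beta-sweep experiment driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
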