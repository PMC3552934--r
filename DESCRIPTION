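Package: semiecol
Title: Constrained Exposure-Disease Estimation for Semi-Ecological Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimators for exposure-disease associations in semi-ecological
    (group-based) study designs where exposure groups are ordered, individual
    exposures are measured with classical additive error, and a large share of
    exposure measurements may be missing at random. Implements the naive
    complete-case analysis, group-based exposure scores (GBS), order-constrained
    group-based scores via weighted isotonic regression (CGBS), and a
    constrained (Monte Carlo) EM estimator for linear and logistic outcome
    models with known measurement-error variance, together with Meilijson
    empirical-information standard errors, a sensitivity-analysis helper, a
    simulation engine for bias/MSE studies, plain-text data input/output and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
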