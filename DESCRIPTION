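Package: logqa
Title: Predicting Portal-Dosimetry Gamma Passing Rates from VMAT Trajectory Logs
Version: 0.1.0
Authors@R:
    person("logqa", "developers", email = "logqa@example.org", role = c("aut", "cre"))
Description: Tools for machine-log-file based virtual patient-specific QA of
    volumetric modulated arc therapy (VMAT). Provides a portable trajectory-log
    container with reader/writer and validation, a synthetic VMAT cohort
    generator with parametric delivery-error injection, thirteen log-derived
    delivery-error and complexity features (axis RMSEs, MU-weighted MLC RMSEs,
    field opening, dose rate, MU per arc, modulation complexity score), an
    idealised fluence engine with global gamma-index analysis at configurable
    dose/distance criteria and low-dose threshold, Spearman correlation
    analysis stratified by treatment site, and a four-model nested
    cross-validation regression benchmark (LASSO, RBF support-vector
    regression, random forest, gradient-boosted trees) for predicting gamma
    passing rates, with split-count feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    glmnet,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
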