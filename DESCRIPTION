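Package: splitaudit
Title: Auditing Train/Test Performance Bias for Classifiers on Limited Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how the random division of a limited
    case-control cohort into training and test sets biases machine-learning
    classifier evaluation. Provides prevalence-balanced repeated
    shuffle-splitting with covariate balance monitoring, repeated nested
    cross-validation with modal hyperparameter and stability feature
    selection, rank-based ROC AUC estimation, train-versus-test AUC tradeoff
    regression, paired permutation model comparison, and incremental-cohort
    learning curves with a formal convergence rule. A synthetic cohort
    generator with analytically known population discriminability (binormal
    calibration) makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
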