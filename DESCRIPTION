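Package: elsar
Title: Ensemble Linear Subspace Analysis for High-Dimensional Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Random covariate-subspace ensembles of penalized linear
    regression predictors (lasso, elastic net, adaptive lasso, LARS and
    SCAD) for prediction when the number of covariates far exceeds the
    sample size. Each ensemble member is fitted on a randomly selected
    subset of covariates and summarised either at a 10-fold
    cross-validated penalty or as a trimmed average of the predictions
    along a fixed 100-value penalty path; member predictions are then
    averaged. Includes the simulation models, mean squared prediction
    error machinery and efficiency tables used to compare the methods
    under random- and fixed-design protocols, plus a small command-line
    driver for reproducible experiment grids.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
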