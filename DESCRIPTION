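Package: mdqr
Title: Minimum-Distance Quantile Regression for Spatial Autoregressive Panel Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-step minimum-distance quantile regression (MDQR) and its
    instrumental-variable variant (IV-MDQR) for spatial autoregressive panel
    data models with individual fixed effects, together with a pooled
    instrumental-variable fixed-effects quantile regression baseline
    (IV-FEQR). Includes a Frisch-Newton interior-point solver for check-loss
    quantile regression, kernel-based sandwich covariance estimation with
    Hall-Sheather or Bofinger bandwidths, construction and validation of
    spatial weight matrices, a simulator for homoscedastic and heteroscedastic
    spatial panel designs, and a Monte Carlo harness reporting bias and RMSE.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
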