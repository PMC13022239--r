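Package: pigwater
Title: Subset ARMAX Modelling of Hourly Water Consumption in Fattening Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling barn-level hourly drinking-water consumption of
    fattening pigs with subset-constrained ARMAX models: a synthetic barn-data
    generator (exact model-truth and calibrated farm-realistic modes), sensor-data
    cleaning rules, harmonic/trend/covariate design matrices, CSS-initialized exact
    Gaussian maximum-likelihood estimation via a state-space innovations filter,
    Wald-based coefficient pruning, information-criterion order selection,
    short-term forecasting with 95 percent prediction intervals, and residual
    diagnostics (Ljung-Box, Shapiro-Wilk, hourly profiles, hour-of-day ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
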