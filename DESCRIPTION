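Package: resvimp
Title: Residual Permutation Importance Tests for Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Explores whether the permutation variable importance (VIMP) of a
    selected predictor in a random forest is partially or totally borrowed from
    correlated predictors. The feature of interest is decomposed into a part
    explained by the remaining predictors and a residual part; out-of-bag
    permutation importance is computed for both, and a subsampling resampling
    test (0.632-rule, without replacement) decides whether the marginal
    importance exceeds the residual importance and whether the residual
    information still contributes to prediction. Includes Gaussian-linear and
    logistic-link simulation designs with controlled correlation and
    semipartial correlation so that type-I error and power studies are
    reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ranger,
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
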