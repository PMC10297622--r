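Package: cpmixed
Title: Tweedie Compound Poisson Mixed Models with Covariate-Dependent
    Random Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits three-level mixed models for semicontinuous (zero-inflated,
    nonnegative) responses in which the conditional response distribution is
    Tweedie compound Poisson with index parameter 1 < p < 2, and the cluster-
    and sub-cluster-level random effects are gamma distributed with means that
    depend log-linearly on covariates observed at their own level.  Regression
    coefficients are estimated by optimal estimating equations solved with a
    Newton scoring algorithm, random effects are predicted by closed-form
    orthodox best linear unbiased predictors, and dispersion parameters are
    estimated by adjusted Pearson moment estimators with exact bias
    corrections.  The package includes an exact hierarchical compound Poisson
    simulator, data validation for multilevel designs, and import/export of
    long-format data, configurations and fitted results.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
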