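Package: statetrait
Title: Penalized Ordinal State-Trait Regression for Intensive Longitudinal Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits cumulative logistic mixed models in which an ordinal response
    depends, through a continuous latent variable, on a person's median (trait)
    level and current (state) level of an ordinal predictor. The latent effect
    surface f(r, s) over trait-state cells is estimated with a quadratic
    difference penalty that shrinks the fit towards the classical linear
    between/within-person disaggregation model, with likelihood-based selection
    of the shrinkage parameter, effective degrees of freedom, latent-scale R
    squared summaries, lagged-response models, and a simulation engine for
    method comparison studies on experience-sampling-like panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    yaml
Config/testthat/edition: 3
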