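Package: obelast
Title: Hierarchical Bayesian Estimation of the Income Elasticity of Obesity Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the country-level income elasticity of adult
    obesity prevalence from country-year panels of prevalence and GDP per
    capita. Implements a two-stage Bayesian hierarchical random-coefficients
    model fitted by a conjugate Gibbs sampler, a functional-form contest
    (linear, quadratic, log-log) scored by mean absolute percentage error, an
    iterative forward selection of macro-environmental moderators under
    AIC/BIC with a correlation screen, Geweke convergence diagnostics, and
    elasticity-draw forecasting of prevalence under income-growth projections
    with policy sensitivity scenarios. Includes a synthetic panel generator
    with recorded ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
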