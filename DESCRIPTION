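Package: gphurdle
Title: Generalized Poisson Hurdle Regression for Zero-Altered, Dispersed Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits hurdle regression models whose positive part follows a
    zero-truncated generalized Poisson distribution, so that count responses
    that are simultaneously zero-inflated (or zero-deflated) and over- or
    under-dispersed can be modelled in one likelihood. Provides exact
    probability mass functions, moments and samplers for the generalized
    Poisson and its hurdle mixture; maximum-likelihood and generalized
    method-of-moments (GMM) estimation driven by a derivative-free
    Nelder-Mead simplex optimizer; bootstrap and Wald inference; AIC model
    comparison against Poisson-hurdle and generalized-Poisson baselines; a
    seeded synthetic-data generator; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
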