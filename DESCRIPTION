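Package: outletndi
Title: Bayesian Shared-Component Index Models for Tobacco and Alcohol
    Retail Outlet Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how tobacco, alcohol, and combined
    tobacco-and-alcohol retail outlet rates relate to neighborhood
    disadvantage across areal units such as census block groups. Includes
    record linkage of retail listings across databases using optimal
    string alignment similarity combined with great-circle distance
    thresholds; preparation of decile-scored sociodemographic covariates
    and expected outlet counts; a Bayesian index regression model with a
    Dirichlet-weighted disadvantage index, shared and outlet-specific
    intrinsic conditional autoregressive spatial effects, and Poisson
    counts, fit by adaptive Metropolis-within-Gibbs; exceedance
    probability risk summaries and population-density category tables;
    and a synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr
Config/testthat/edition: 3
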