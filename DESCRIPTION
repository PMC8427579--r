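Package: ingrowth
Title: Hierarchical Negative-Binomial Modeling of Tree Recruitment from
    Repeated Forest Inventories
Version: 0.1.0
Authors@R:
    person("Forest", "Demography Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyze tree recruitment (in-growth) from repeated
    forest-inventory tree lists. Derives stand-structure covariates (basal
    area, stem density, basal-area-weighted shade-casting ability) and
    site covariates (seasonal degree-day sum, Thornthwaite seasonal water
    balance with slope/aspect correction, soil bucket size), groups
    species by shade and drought tolerance with seeded k-means, and fits
    a hierarchical negative-binomial count model with trait-group
    coefficients, plot and species random effects, and exposure offsets
    using a built-in adaptive MCMC sampler. Includes convergence
    diagnostics (rank-normalized split R-hat, effective sample size),
    randomized quantile residuals, count-family comparison, posterior
    effect curves and interaction surfaces, and a synthetic-inventory
    generator for end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
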