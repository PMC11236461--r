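Package: fragsar
Title: Simulation-Based Benchmarking of Richness and Beta-Diversity
    Estimators in Fragmented Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates fragmented-landscape metacommunities (patch areas from
    a four-parameter beta distribution, log-normal species abundance
    distributions, species-specific area responses, capacity-constrained
    assignment of individuals to patches) and imperfect transect-based
    sampling with repeated binomial surveys.  Provides three estimation
    routes for patch-level species richness and pairwise Sorensen
    similarity: observed pooled counts, abundance-based asymptotic
    Chao/Hill (q = 0) estimators, and a data-augmented hierarchical
    multi-species occupancy model fitted by Markov chain Monte Carlo.
    Fits power-law species-area relationships and logit-link beta-diversity
    regressions from any of the three routes and scores estimator bias,
    accuracy and precision across factorial detection scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
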