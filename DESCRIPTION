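Package: saeprev
Title: Small-Area Estimation of Survey Prevalence with Spatial Smoothing
    and Geographic Multiple Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-based direct estimation of small-area prevalence from
    complex survey data, hierarchical Bayesian spatial smoothing of
    empirical-logit transformed direct estimates with BYM
    (ICAR + unstructured) random effects fit by Gibbs sampling,
    conditional-predictive-ordinate model comparison, multiple imputation of
    missing small-area geography from zip-to-tract crosswalk ratios, and
    population-share assignment of respondents to reporting areas. Includes a
    synthetic-county generator (grid geography, spatially correlated true
    prevalence, informative sampling, covariate-dependent geocode
    missingness) so the full pipeline can be exercised and validated without
    restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
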