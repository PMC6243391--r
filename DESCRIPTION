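Package: turftraits
Title: Trait Variation, Plasticity and Community Convergence in Turf-Transplant Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for leaf functional trait data from reciprocal
    turf-transplant experiments along elevation gradients. Provides trait
    cleaning rules for unrealistic leaf measurements, nested variance
    partitioning of trait variation across taxonomic levels and populations,
    biomass-weighted nonparametric bootstrapping of community trait
    distributions with a trait-data priority hierarchy and congener
    rarefaction, a simplified relative distance plasticity index with
    stratified permutation inference, and classification of transplant
    responses as converging toward or diverging from destination community
    trait means with G-test (log-likelihood ratio) contingency analysis.
    Includes a synthetic-data generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
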