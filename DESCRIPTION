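Package: issrpop
Title: Population Genetics of Dominant Binary Markers with Conservation
    Risk Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dominant binary (presence/absence) marker
    data such as ISSR or AFLP band matrices scored on multiple populations.
    Implements Lynch-Milligan allele-frequency estimation, per-population
    diversity statistics (He, Shannon I, polymorphism, private alleles),
    Nei's Gst, distance-based AMOVA with permutation testing, Crow-Aoki
    gene flow, Mantel tests for isolation by distance, minimum spanning
    networks on Hamming distances, PCA/DAPC ordination, a Bayesian admixture
    sampler for binary band phenotypes with Evanno delta-K model choice,
    seeded decline and local-extinction scenario simulations, and rule-based
    conservation risk scoring (Mexican MER and a simplified IUCN mapper).
    A calibrated hierarchical Balding-Nichols simulator generates synthetic
    band matrices with known truth for testing and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
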