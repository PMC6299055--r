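Package: podnet
Title: Social Network Analysis of Photo-Identification Encounter Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the social structure of individually
    identifiable animals from "gambit of the group" photo-identification
    encounter records, as used in studies of small resident cetacean
    populations. Computes half-weight association indices (HWI) and their
    gregariousness-corrected variant (HWIG), tests for non-random
    association with Manly-Bejder within-sample matrix permutations,
    estimates standardized lagged association rates (SLAR) with temporal
    jackknife errors and fits exponential models of social organisation by
    QAIC, delineates social clusters by average-linkage clustering and
    Newman eigenvector modularity, computes node- and cluster-level network
    metrics, estimates social differentiation by beta-binomial maximum
    likelihood, and summarises diel habitat partitioning and
    fishery-interaction patterns by cluster. A fission-fusion society
    simulator with known ground truth supports validation and power
    analysis of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    yaml,
    ape,
    mclust,
    Rcpp
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
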