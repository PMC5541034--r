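Package: rumicol
Title: Successional Microbial Colonization Analysis for Artificial Rumen Experiments
Version: 0.1.0
Authors@R:
    person("Rumicol", "Developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing successional microbial
    colonization of forage in rumen-simulation (Rusitec) experiments: 15N
    stable-isotope partitioning of plant-residue nitrogen into microbial and
    feed fractions, alpha diversity and rarefaction of genus/OTU count tables,
    Bray-Curtis dissimilarity with UPGMA clustering and principal coordinates,
    PERMANOVA for factorial repeated designs with permutation of residuals
    under a reduced model, canonical correspondence analysis against
    fermentation covariates, time-stratified Spearman co-occurrence networks
    with edge-betweenness communities and complexity metrics, and FTIR
    metabolome fingerprint preprocessing (Savitzky-Golay derivatives) with
    distance-based multivariate tests. A synthetic-data generator emulates the
    2x2 factorial repeated-measures design so that every stage is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
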