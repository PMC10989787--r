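Package: keystones
Title: Keystone Species Identification from Cross-Sectional Microbiome
    Data via Causal Lotka-Volterra Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies keystone species in cross-sectional microbiome
    cohorts. Builds a compositionality-aware co-occurrence prior (SparCC
    basis correlations with permutation significance), fits a generalized
    Lotka-Volterra interaction model to near-steady-state abundance
    profiles by confounder-adjusted ridge regression with iterative
    permutation pruning, scores hub species with HITS under a permutation
    null, simulates in-silico interventions (species removal or addition)
    by integrating the fitted dynamics to a new equilibrium, and greedily
    selects the minimal species combination whose joint intervention
    maximally restores a diseased community toward a healthy reference.
    Includes Wilcoxon/AUC differential-abundance analysis, KEGG-module
    Fisher enrichment, and a planted-truth synthetic community generator
    used as the test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    igraph,
    deSolve,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    optparse
Config/testthat/edition: 3
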