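Package: pr2sim
Title: Kinetic Simulation of Mutation-Rate-Driven Compliance with Chargaff's Second Parity Rule
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic models linking the twelve directed base-mutation
    rate constants of a double-stranded DNA genome to its compliance with
    Chargaff's second parity rule (PR-2). Implements the general 4-state
    mutational ODE network and its no-strand-bias (NSB) reduction with
    closed-form equilibria, the 16-state dinucleotide (dyad) hypercube network
    and its equilibrium class structure, seeded Monte Carlo sampling of rate
    constants and initial compositions, GC/AT skew metrics with per-kingdom
    PR-2 tolerance boxes, time-to-compliance versus time-to-equilibration
    analysis, a set of twelve generalized linear constraint relations among the
    rate constants, FASTA-based genome content counting, and synthetic-genome
    and rate-ensemble generators for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
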