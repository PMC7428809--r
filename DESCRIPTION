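Package: cryptsim
Title: Multiscale Stochastic Simulation of Stem-Cell and Crypt Metapopulation
    Dynamics in Epithelial Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based microsimulation of tissue stem cells organized into
    intestinal-crypt-like proliferative units on a hexagonal lattice. Stem
    cells divide symmetrically and asymmetrically and are lost under
    homeostatic feedback; crypts go extinct and are replaced by fission of
    neighbors, creating a metapopulation dynamic. Cells accumulate beneficial,
    deleterious and mutator mutations with multiplicative fitness effects, and
    runs end at biallelic inactivation of a tumor suppressor gene (tumor
    initiation), tissue extinction, or censoring. Includes replicate drivers,
    parameter sweeps, and outcome statistics: Kaplan-Meier based cumulative
    hazard of initiation, mutator fixation fractions, crypt turnover and
    fitness summaries, and spatial mutator agreement by lattice distance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    survival,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
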