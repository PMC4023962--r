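Package: divergrass
Title: State-Dependent Diversification Analyses for Time-Calibrated
    Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests whether a binary trait such as C4 photosynthesis is
    associated with elevated lineage diversification on time-calibrated
    phylogenies.  Implements the binary-state speciation-extinction
    (BiSSE) likelihood with proportional sampling fractions or terminally
    unresolved clades, constrained model families with likelihood-ratio
    and AICc comparison, stepwise AICc detection of birth-death rate
    shifts on genus-level trees with assigned species richness
    (MEDUSA-style), sister-clade richness contrasts with exact Wilcoxon
    signed-rank tests, composite-tree assembly (rescaling, grafting,
    genus collapsing) with richness bookkeeping, and state-dependent
    birth-death tree simulators used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    deSolve,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
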