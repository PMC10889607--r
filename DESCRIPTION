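Package: bnsynergy
Title: Cell-Line-Specific Boolean Network Models of Drug-Combination Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds cell-line-specific Boolean models of cancer signalling
    networks from a signed interaction graph plus mutation and expression
    profiles, simulates uniform-asynchronous update ensembles to an
    entropy-detected steady state under single- and paired-drug
    perturbations, and scores drug-pair synergy. Per-protein synergy scores
    (PSS) computed on steady-state activities over a dose-probability grid
    are aggregated into a predicted highest-single-agent (HSA) synergy
    score through a genetic-algorithm-selected protein subset, and PSS
    profiles are clustered into mechanism groups. Includes a synthetic
    scenario generator with a hidden ground-truth model and an exact
    asynchronous Markov-chain oracle for verifying the stochastic
    simulator on small networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml,
    ape,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
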