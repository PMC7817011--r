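Package: angiosprout
Title: Hybrid Multiscale Stochastic Simulation of Early Sprouting Angiogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid two-dimensional stochastic multiscale model of early
    sprouting angiogenesis. Endothelial cells carry an intrinsic stochastic
    VEGF-Delta-Notch gene-expression circuit with non-local juxtacrine
    cross-talk, migrate as a persistent random walk on a hexagonal lattice
    with von Mises polarity, cell-cell adhesion and overtaking, and remodel
    dynamic extracellular-matrix fields (collagen density, basement-membrane
    deposition, fibril orientation landscape). The coupled system is simulated
    with a Next-Subvolume event engine. The package ships the bifurcation
    analysis of the signalling circuit, trajectory metrics (displacement,
    orientation, directionality, tip-cell proportion, the network mixing
    measure), vascular-network morphometrics, canned experimental setups
    (plexus sprouting, VEGF gradients, cell-bead invasion, linear-sprout
    cell-competition assays with receptor-mutant lineages and DAPT treatment)
    and a one-at-a-time parameter sensitivity sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
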