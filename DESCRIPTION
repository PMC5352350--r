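Package: habm
Title: Hybrid Multiscale Agent-Based Model of Multiple Myeloma in the Bone
    Marrow Microenvironment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multiple-myeloma growth, immune surveillance and
    drug response in a 3D bone-marrow microenvironment using a hybrid
    multiscale model: intracellular Hill-kinetics ODE systems for
    SDF-1-triggered bone-marrow stromal cell (BMSC) stiffening and for
    stiffness/bortezomib-dependent adhesion and survival of
    myeloma-initiating cells (MIC), coupled to a stochastic lattice
    agent-based model of five cell compartments (BMSC, MIC, MM, CD8+ CTL,
    Treg) with reaction-diffusion SDF-1 and TGF-beta fields. Includes
    genetic-algorithm parameter estimation with local sensitivity and
    uncertainty analyses, three-drug (bortezomib, lenalidomide,
    thalidomide) treatment simulation over factorial dose grids, and a
    three-drug synergy index with synergistic/additive/antagonistic
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
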