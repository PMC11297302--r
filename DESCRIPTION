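Package: holimap
Title: Linear-Mapping Approximations for Stochastic Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting molecule-number distributions in stochastic
    models of gene regulatory networks. Nonlinear protein-gene, protein-protein
    and RNA-RNA interactions are mapped by conditional moment-matching onto
    effective linear (telegraph-type) networks whose chemical master equation
    is solved by finite state projection. Implements the linear-mapping
    approximation and its high-order refinements (2-, 3- and 4-parameter
    variants), an exact stochastic simulation algorithm with geometric
    translational bursting, a hybrid simulation/moment-matching method for
    large networks, and diagnostics for distribution accuracy (Hellinger
    distance), bimodality and deterministic stability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    deSolve,
    methods,
    pracma,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
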