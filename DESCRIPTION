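Package: ctrlnet
Title: Network Control Analysis of Brain State Transitions on Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing transitions between whole-brain activation
    topographies as a linear network control problem on a structural
    connectome. Implements adjacency normalization, optimal control energy
    between state pairs (closed-form two-point boundary value solution),
    Gramian-based minimum control energy, regionally heterogeneous control
    inputs derived from modulation maps (receptor density, cortical-thickness
    effect sizes), distance-dependent consensus connectome construction,
    effective resistance and network variance, degree- and
    geometry-preserving rewired network null models, spin-rotation spatial
    null models, transition asymmetry / variability / relay statistics,
    permutation tests, partial rank correlations and dominance analysis, plus
    seeded synthetic-data generators that emulate every input the analysis
    assumes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
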