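Package: stickysim
Title: Individual-Based Simulation of Sticky-Cell Differentiation and
    Bacterial Surface Colonization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An individual-based model of bacterial surface colonization in
    which cells in a well-mixed liquid and on a two-dimensional lattice can
    express a costly adhesive ("sticky") phenotype. Cells differentiate under
    one of three strategies (fixed allele, probabilistic switching, or an
    evolvable threshold decision rule on niche and local stickiness), divide,
    die, and migrate between liquid and surface. The package provides the
    stochastic engine (compiled), lattice geometries with three to eight
    neighbours, mutation and strategy classification, spatial pattern and
    life-cycle metrics, evolutionary parameter sweeps, competition assays
    between fixed genotypes, delimited-text input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
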