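Package: fibrocyteCA
Title: Stochastic Cellular-Automaton Model of Fibrocyte-CD8 T Cell
    Dynamics in Peribronchial Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the joint dynamics of CD8+ T cells and fibrocytes in
    the peribronchial lamina propria with a probabilistic cellular automaton
    on an annular lattice (infiltration, contact-induced division,
    crowding-dependent death, chemotactically biased movement, annual
    exacerbation bursts), over multi-year horizons for healthy, COPD and
    therapy scenarios.  Includes a mean-field companion model used to
    calibrate per-step rates against observed tissue densities, a spatial
    quantification suite for two-class cell point patterns (dilation-radius
    interaction density, nearest-neighbour distance statistics,
    distance-thresholded Delaunay cluster detection with ROI-edge removal,
    random-placement null model), live-imaging track metrics, and generators
    for synthetic histology-like point patterns and motility tracks.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
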