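Package: dyadrot
Title: Kinematics and Stochastic Simulation of Sibling Cell-Pair Rotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies planar rotations of nascent sibling hair-cell pairs in
    zebrafish neuromasts from videomicroscopy-derived tracking tables: per-frame
    positional angles, cumulative turn and arc length, four-parameter logistic
    phase segmentation with tangent-intersection phase boundaries, overshoot,
    wobbling and trajectory-noise statistics, genotype-level statistical
    comparison, pair circularity and interface-shape chirality classification,
    dynamic cell-neighbor topology, and epithelium-wide movement correlation.
    Includes a synthetic tracking-data generator emulating the study conditions
    and a Metropolis-Hastings two-cell model with Gaussian attractor wells and
    soft-sphere repulsion on a circular lattice.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
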