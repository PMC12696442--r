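Package: tpmscaffold
Title: Design and Image-Based Morphometry of Triply Periodic Minimal
    Surface Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates Gyroid, Schwarz Diamond and Schoen I-WP triply
    periodic minimal surface (TPMS) scaffolds from their trigonometric
    nodal equations, calibrates the level-set threshold so the voxelized
    design reaches a prescribed porosity, and exports watertight
    print-ready STL meshes. The imaging half renders voxel models into
    binarized axial slice stacks that emulate reconstructed micro-CT
    output, builds analytic phantoms with known ground truth, and
    quantifies architecture the way an ImageJ workflow does:
    region-of-interest slice porosity and per-pore Equivalent Circular
    Diameter via connected-component labeling with a minimum-size noise
    filter, aggregated as mean and standard deviation with cross-geometry
    comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
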