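Package: voxdivide
Title: Stochastic Voxel-Based Simulation of Plant Cell Division Planes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates plant cell division in arbitrary 3D (and 2D) cell shapes
    with a discrete-space, cellular-Potts-style model: division is a binary
    partition of the voxelized mother cell, obtained by Metropolis minimization
    of an energy combining a volume-ratio constraint and the area of the
    interface between daughter cells. Includes synthetic shape digitization,
    label-stack input/output, interface mesh extraction and plane-level
    geometry (area, normal, centroid distance), a 16-feature cell
    morphometrics suite, ensemble normalization statistics, the nested
    centroid-then-minimal-area division rule, and recursive multi-generation
    embryogenesis simulation with lineage bookkeeping and spatial annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
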