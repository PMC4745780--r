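Package: organotrack
Title: Automated Tracking and Morphometry of Tumor Organoid and Fibroblast 3D Co-Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for three-dimensional tumor
    organoid / cancer-associated fibroblast (CAF) co-cultures imaged by
    two-channel live-cell time-lapse microscopy and confocal stacks.
    Provides phase-correlation video stabilization, median and non-local
    means denoising, local adaptive threshold segmentation of fibroblast
    cohorts, Farneback dense optical flow motility quantification,
    convexity-defect branching morphometrics, Markov random field
    segmentation of confocal channels by alpha-expansion graph cuts,
    per-organoid morphometric parameters with group statistics, and a
    synthetic phantom generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    png,
    yaml,
    igraph,
    EBImage,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
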