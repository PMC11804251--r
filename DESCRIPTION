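Package: tomopick
Title: Centroid-Based Particle Picking in Cryo-Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for detecting macromolecular particle centroids in
    cryo-electron tomograms by heatmap regression. Renders summed two-Gaussian
    centroid labels from coordinate annotations, rescales and robustly
    normalizes tomograms, splits them into overlapping training cubes with
    class balancing, trains a pluggable volumetric backbone under a composite
    weighted-Huber plus spatial-gradient loss, performs tiled inference with
    overlap stitching, extracts centroids by neighbourhood peak detection with
    optional mask gating, and scores predictions against ground truth with
    optimal-assignment matching, precision/recall/F1 and diameter-normalized
    RMSE including a confidence-percentile sweep. Reads and writes MRC volumes,
    RELION-style STAR coordinate tables and plain-text point lists, and ships a
    phantom-tomogram simulator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
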