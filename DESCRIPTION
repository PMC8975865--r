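Package: creekmorph
Title: Tidal Creek Network Extraction and Morphometrics from Elevation Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated extraction and parametrisation of tidal creek
    networks in coastal wetlands from gridded elevation data (lidar-derived
    digital surface models). Detects creeks by combined elevation and slope
    thresholds, repairs and skeletonizes the creek mask, assigns reverse
    Strahler orders by iterative pruning from the entry channel, and computes
    per-segment, per-order and whole-network morphometric parameters
    (drainage density, overmarsh path length, channel lengths, cross-section
    width/depth/area, sinuosity, tidal prism, main channel gradient).
    Includes tidal-level interpolation from port tables, a threshold
    sensitivity analysis, an elevation-change-versus-creek-distance analysis,
    and a synthetic marsh generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
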