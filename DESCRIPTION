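Package: mangrovedyn
Title: Mapping, Accuracy Assessment and Change Analysis of Fringing
    Mangrove Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for very-high-resolution habitat mapping of fringing
    mangrove along volcanic coastlines: polygon shape-complexity metrics
    (perimeter/area ratio, boundary-amplitude and convexity scores, node
    counts), map-accuracy assessment (buffered random-point validation,
    confusion matrices, overall accuracy, Cohen's kappa, pairwise
    two-proportion Z tests, digitizer quality control, survey sample-size
    design), semi-automatic classification chains (Gaussian maximum
    likelihood with optional land/sea partitioning, NDVI masking and
    region-growing segmentation, raster-to-polygon conversion with a
    minimum-mapping-unit filter), spatio-temporal analysis of moving
    polygons between two epochs (stable, expansion, contraction,
    generation and disappearance events), coast-referenced coverage
    statistics, and a seeded synthetic coastal-landscape generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    geosphere,
    MASS,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
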