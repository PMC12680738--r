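Package: streamhab
Title: Drone Survey Planning and Multi-Metric Stream Habitat Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the physical habitat health of small
    streams from drone-derived vector data.  Plans obstacle-aware
    boustrophedon survey flight routes with image-overlap driven line
    spacing, grid-based detouring and battery budgeting; extracts
    spatially continuous habitat parameters (wetted width, bank-top
    width, erosion, riparian buffer, in-stream cover, depth, pools,
    bends, sinuosity, gradient) from delineated bank and layer
    geometries via an equidistant medial-axis centerline; and scores
    nine physical metrics into a multi-metric habitat health index with
    continuous, transect and vicinity-window assessment modes.  A
    parametric meandering-channel generator with analytically known
    ground truth supports fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
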