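Package: caimseg
Title: Activity-Based Level-Set Segmentation of Calcium Imaging Videos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects regions of interest (somata and neurites) in two-photon
    calcium imaging videos with multiple coupled active contours evolved by
    the level set method. Each contour partitions its local neighbourhood
    into a cell interior and a narrowband exterior whose average time
    courses act as region features; contours of nearby cells are coupled in
    a way that permits interiors to overlap, so that mixed pixels are
    explained by the sum of the overlapping cells' time courses. Includes
    automatic seeding from correlation and mean summary images, merging and
    pruning of redundant estimates, extraction of raw and neuropil time
    courses, segmentation and spike-timing evaluation metrics, and a seeded
    synthetic-video generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    EBImage,
    clue
Suggests:
    testthat (>= 3.0.0),
    withr,
    rhdf5,
    jsonlite,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
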