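Package: droughtvision
Title: Tiled Detection, Bio-Inspired Network Blocks and Synthetic
    Chlorophyll-Fluorescence Scenes for Drought-Stress Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drought-stress detection on chlorophyll-fluorescence
    (Fv/Fm) imagery of plant seedlings. Implements compound-eye mosaic tiling
    with exact YOLO-convention label remapping between the mosaic canvas and
    per-tile coordinate frames, multi-scale linear attention and large-kernel
    CMUNeXt feature-map blocks with a pure-R forward/backward engine, the
    Inner-CIoU auxiliary-box regression loss with a dynamic ratio schedule,
    a detection metric suite (precision, recall, F1, all-point-interpolated
    average precision, mAP over IoU thresholds), assembly of a small
    single-stage detector from a layer table with parameter-count accounting,
    and a synthetic Fv/Fm drought-scene generator with a split-then-augment
    dataset builder graded by soil relative humidity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
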