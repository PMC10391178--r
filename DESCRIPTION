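Package: teadetect
Title: Dense Small-Object Detection for Multimodal Plant Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for real-time dense small-object detection in aligned
    RGB / infrared / depth plant imagery, built around an improved
    one-stage (YOLOv5s-family) detector. Provides exact parameter and
    floating-point-operation accounting for every architectural variant,
    data-layer and feature-layer multimodal fusion operators including a
    frequency-domain cross-modal attention module (FFA), object-based
    scale matching for transfer learning between datasets with different
    object-scale distributions, aligned-triplet and annotation input and
    output (PNG, COCO JSON, YOLO text), a seeded synthetic scene
    generator emulating dense tiny-object field imagery, and a CPU
    reference training and evaluation loop (CIoU loss, anchor
    assignment, precision/recall/mAP).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    tools,
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    EBImage,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
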