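Package: fracdet
Title: Toolkit for X-Ray Fracture Detection Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Building blocks for single-class fracture detection in
    radiographs: YOLO-format dataset input/output with deterministic
    train/validation/test splitting, a radiograph phantom generator that
    emits bone-like images with fracture lines and exact bounding-box
    labels, a content-aware augmentation pipeline (geometric transforms
    with label propagation, blank-area detection, edge-colour inference,
    mean fill and Poisson gradient-domain refinement), the Bone-MSCA
    multi-scale convolutional attention block (directional strip
    convolutions, dilated diagonal convolutions, deformable convolution,
    Sobel edge gating and squeeze-and-excitation recalibration), the
    IoU/CIoU/SIoU bounding-box loss family with Focal weighting and
    analytic gradients, detection metrics (precision, recall, F1, average
    precision, mAP50), and exact parameter/FLOP accounting for the nano
    detector architecture the blocks target.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
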