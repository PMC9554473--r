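Package: spikedet
Title: Attention-Augmented Single-Stage Detection and Counting of Wheat Spikes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates a single-stage convolutional detector
    for counting wheat spikes in field images. The network is a compact
    CSP-Darknet detector (Focus stem, C3 blocks, spatial pyramid pooling,
    FPN+PAN neck, three-scale head) augmented with efficient channel attention
    (ECA) gates inside the backbone C3 blocks and a global attention mechanism
    (GAM) in front of each prediction convolution. Includes exact per-layer
    trainable-parameter accounting, CIoU bounding-box regression loss,
    detection and counting metrics (precision/recall, interpolated average
    precision, RMSE, MAE, relative count error), the standard preprocessing
    pipeline (mosaic augmentation, minimal-padding letterbox rescaling,
    k-means anchor fitting with a best-possible-recall gate, image tiling),
    Pascal VOC XML and YOLO txt annotation I/O, and a deterministic generator
    of synthetic wheat-field scenes with dense, mutually occluding spikes for
    testing without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    png,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
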