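Package: homecagenet
Title: Dual-Stream Spatiotemporal Networks for Home-Cage Mouse Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, trains and evaluates dual-stream spatiotemporal
    convolutional networks for behavioral classification of singly-housed
    mice from home-cage video. Implements a feature-sharing scheme that
    jointly processes the RGB and optical-flow streams at regular intervals,
    five reference architectures (a plain 3D-CNN baseline, two
    Inception-v3-block-D variants with self-attention or bidirectional-LSTM
    heads, and two purely Inception-based reinforced-stream networks), the
    full preprocessing pipeline (frame resizing and cropping, temporal
    downsampling, day-to-night appearance normalization, Farneback dense
    optical flow, cuboid assembly), class-weighted training with
    learning-rate plateau scheduling, multi-metric evaluation and
    inference-time ensembling, plus a synthetic clip generator with
    class-specific motion so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    Rcpp,
    utils,
    generics,
    rlang,
    tibble,
    jsonlite,
    yaml,
    ggplot2,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
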