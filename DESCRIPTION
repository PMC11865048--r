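Package: seednet
Title: Seed Photograph Classification with Lightweight Attention CNNs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for classifying crop seed varieties from RGB
    photographs of seeds arranged on a dark background. Provides fixed-threshold
    segmentation and per-seed cropping, offline dataset augmentation (brightness,
    Gaussian noise, mirroring, rotation) with a stratified 8:1:1 split, a
    from-scratch implementation of the MobileNetV2 inverted-residual backbone and
    its HPMobileNet variant (depthwise Mish/Sigmoid gating blocks, efficient
    channel attention, Mish activations), an analytic parameter/FLOP profiler, an
    SGD training loop with a step-decay ("95-Gradient") learning-rate schedule,
    confusion-matrix metrics, and Grad-CAM heatmaps. Includes a synthetic
    seed-scene generator so the full pipeline is testable without real imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    Rcpp,
    stats,
    grDevices,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
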