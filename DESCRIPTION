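Package: pneumonet
Title: Attention-Ensemble Dual-Backbone Convolutional Classifier for
    Pneumonia Detection in Chest X-Rays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and interprets a dual-backbone convolutional
    classifier for two-class chest X-ray images (normal vs pneumonia).
    Features from an EfficientNetB0 and a DenseNet121 branch (or a compact
    CPU-friendly test backbone) are refined by multi-head self-attention,
    combined by a channel-attention feature-fusion block, enhanced by a
    residual block and a channel-wise attention gate, condensed by dynamic
    attention pooling, and classified by a regularized softmax head. The
    package ships the full preprocessing pipeline (histogram equalization,
    affine augmentation, class weighting), a seeded synthetic X-ray fixture
    generator so every component runs on one CPU without downloads,
    confusion-matrix metrics with truncation-matching recovery of printed
    results, stratified cross-validation, tree-structured Parzen estimator
    hyperparameter search, and Grad-CAM heatmaps on named internal layers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    withr,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
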