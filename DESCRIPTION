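Package: kernseg
Title: Kernel-Enhanced Convolutional Networks for Ultrasound Nerve Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Semantic segmentation of nerve structures in 2D ultrasound
    images with a random-Fourier-features (RFF) kernel layer inserted into
    fully convolutional, U-net and residual U-net architectures. Provides a
    seeded generator of speckled ultrasound-like images with nerve masks, a
    small CPU convolutional-network engine with Dice-loss training, overlap
    and ROC evaluation metrics, a Grad-CAM++ extension for segmentation
    with explanation-map relevance statistics (Increase Confidence, Win),
    and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
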