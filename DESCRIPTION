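Package: munetseg
Title: Attention-Augmented Encoder-Decoder Segmentation of Colorectal Polyps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the mu-Net convolutional encoder-decoder for binary
    polyp segmentation in colonoscopy images: multi-branch mu-blocks built from
    residual, dual- and tri-dilated, and split (1xN / Nx1) convolution units,
    each refined by a convolutional block attention module (CBAM) applying
    channel then spatial attention.  Ships its own CPU compute core (GEMM-based
    dilated convolutions with analytic backpropagation, batch normalisation,
    AdamW), the Dice/IoU/pixel-accuracy/precision/recall metric suite, a
    Kvasir-SEG-layout data pipeline with Lanczos-3 resizing and joint
    image/mask augmentation, a seeded synthetic lesion generator for offline
    testing, Grad-CAM and saliency explanations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    jpeg,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
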