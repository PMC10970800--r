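Package: rirsr
Title: Residual-in-Residual Convolutional Super-Resolution for Grayscale
    Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-image super-resolution for 8-bit grayscale
    radiograph-like images using a residual-in-residual convolutional
    network with inception-style multi-kernel residual blocks, dense
    feature fusion and pixel-shuffle upsampling. Includes the matching
    degradation forward model (antialiased bicubic downsampling at x2,
    x4 and x8 plus salt-and-pepper noise), LR/HR patch-pair extraction,
    an L1/Adam patch-based training loop, PSNR/SSIM/multi-scale
    similarity metrics against a bicubic baseline, a seeded phantom
    generator for self-contained experiments, and an ablation driver
    for the channel-attention / concatenation / skip-connection
    variants of the residual block.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
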