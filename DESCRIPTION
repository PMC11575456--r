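Package: hairbench
Title: Synthetic-Hair Benchmark Generation and Learned Hair Removal for Dermoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Procedural generation of paired (hair-free, hairy, mask) dermoscopic
    benchmark images from cubic Bezier hair strands, a U-Net style convolutional
    inpainting model trained with a five-component composite loss (hair-region MSE,
    non-hair MSE, image-normalised hair error, SSIM and total variation), and an
    evaluation suite (MSE, MAE, SSIM, MS-SSIM, near-mask precision/recall/F1)
    including a classical Dullrazor morphological baseline and a hair-count
    robustness sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
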