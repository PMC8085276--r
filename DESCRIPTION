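Package: caldenoise
Title: Model-Blind Spatiotemporal Denoising for Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for denoising two-photon calcium imaging movies with a
    residual spatiotemporal convolutional network trained in two stages:
    supervised pre-training on synthetically corrupted reference frames
    (mixed Poisson-Gaussian noise), followed by model-blind noise-to-noise
    fine-tuning on raw four-frame sequences. Includes a synthetic movie
    simulator (soma-like cells with exponential calcium-transient kinetics,
    shot and read noise, rigid and elastic motion), dataset builders,
    training with Adam, and spatial (PSNR, SSIM) and temporal (delta-F/F,
    transient signal-to-noise ratio) quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
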