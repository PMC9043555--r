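Package: usdespeckle
Title: Speckle Noise Suppression for Breast Ultrasound Images with a 3D
    Convolutional Denoiser
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end speckle noise suppression for grayscale ultrasound
    images and small volumes. Implements a grayscale-mean-driven piecewise
    log/exponential contrast transform, guided-filter detail enhancement,
    high-pass spatial sharpening control, and a small 3D convolutional
    denoising network trained with an L1 plus edge-sensitive objective.
    Ships a synthetic phantom and multiplicative gamma speckle generator so
    the whole method can be trained and evaluated without clinical data,
    together with the standard image quality metrics (MSE, SNR, PSNR, edge
    preservation index, false recognition rate, suppression time).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    RNifti,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
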