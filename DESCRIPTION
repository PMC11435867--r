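Package: cottonhsi
Title: Hyperspectral Detection of Foreign Fibers in Seed Cotton
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for recognizing foreign fibers (plastic film, rope, paper,
    foam) in seed cotton from visible/near-infrared hyperspectral image cubes.
    Implements ENVI raster input/output, a synthetic scene simulator with
    dark/white reference frames, the five-stage spectral preprocessing chain
    (black-and-white reflectance correction, cropping, per-band
    standardization, multiplicative scatter correction, and PCA band
    reduction), center-labeled patch dataset construction with stratified
    splitting, a double-hierarchical residual convolutional network with
    squeeze-and-excitation channel attention trained by Adadelta (implemented
    natively over BLAS matrix products), and confusion-matrix evaluation with
    per-class recall/precision, average accuracy, and overall accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
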