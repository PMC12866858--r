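Package: msifuse
Title: Super-Resolution Fusion of Mass Spectrometry Imaging and Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fuses a low-resolution mass spectrometry imaging (MSI) ion image
    with a co-registered high-resolution microscopy image of the same plant
    tissue section into a single super-resolution chemical image. A small
    residual convolutional network is fitted to each registered image pair
    under a weighted sum of mean-squared-error loss against the interpolated
    ion image and an edge perceptual loss against the microscopy input, with
    early stopping driven by the edge loss. Includes imzML/CSV/TIFF input and
    output, a seeded synthetic tissue phantom generator, PSNR/SSIM checkpoint
    evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
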