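Package: medfuse
Title: Saliency-Guided Multi-Scale Attention Fusion of CT and MRI Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fuses co-registered CT and MRI images with a siamese
    multi-scale dense convolutional encoder, parallel dual-pooling channel
    and spatial attention, a visual-saliency feature fusion rule, and a
    convolutional decoder, trained by image reconstruction under a mixed
    pixel and gradient loss. Includes a seeded CT/MRI phantom generator and
    the six standard fusion-quality metrics (correlation coefficient,
    mutual information, spatial frequency, phase congruency, nonlinear
    correlation information entropy, and the sum of correlations of
    differences).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    stats,
    tools,
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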