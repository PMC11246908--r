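Package: lumbometry
Title: Automatic Measurement of Lumbosacral Radiographic Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automatic measurement of sagittal alignment parameters on
    lateral lumbar radiographs: lumbar lordosis (LL), sacral horizontal
    angle (SHA), intervertebral space angle (ISA) at L4-L5 and L5-S1, and
    percentage of lumbar spondylolisthesis (PLS).  Provides a multi-scale
    attention segmentation network for labelling lumbar vertebrae and the
    sacrum, Harris-corner landmark extraction from segmentation masks, the
    angle and slip geometry computed from a ten-point landmark vocabulary,
    agreement statistics (ICC, PCK, Dice, MAE/RMSE), and a synthetic
    phantom generator with analytic ground truth so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
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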