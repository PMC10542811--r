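Package: edgeseg
Title: Memory-Efficient Binarized Ultrasound Bladder Segmentation and Volume Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, training and evaluating memory-efficient
    bladder-segmentation networks intended for wearable ultrasound devices.
    Implements a lightweight U-Net with depthwise separable convolutions in
    full-precision, binarized (RSign/PReLU) and fully quantized variants whose
    inference path uses no floating-point multiplies; lossless compression of
    quantized skip-connection feature maps (zero-value, differential zero-value,
    bit-plane and extended bit-plane coding); memory and multiply-accumulate
    accounting for edge deployment; a synthetic B-mode phantom generator with
    known ellipsoid volumes; double-area urine-volume estimation from paired
    sagittal/transverse segmentations; and Bland-Altman and concordance
    agreement statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    optparse,
    png,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
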