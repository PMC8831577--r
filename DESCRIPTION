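Package: eatseg
Title: Epicardial Adipose Tissue Segmentation and Quantification from
    Non-Contrast Cardiac CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to segment and quantify epicardial adipose tissue (EAT)
    in non-contrast CT calcium score volumes. Implements Hounsfield-unit
    attention windowing to 8-bit, a bisected look-ahead slab sequencing of
    axial heart slices, a pluggable per-slice semantic segmentation contract
    with a small CPU-trainable encoder-decoder reference model, fat-window
    thresholding inside the pericardial sac, and a full agreement-evaluation
    toolkit (slice and volume Dice, IOU, quartile slice grouping,
    Bland-Altman, origin-constrained regression, percent error, paired t).
    A synthetic cardiac phantom generator with analytic ground truth makes
    every pipeline stage testable without clinical data; minimal DICOM
    series and NIfTI mask input/output are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
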