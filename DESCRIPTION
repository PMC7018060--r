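Package: renalqct
Title: Size-Corrected Quantitative CT Assessment of Renal Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying renal cortical fibrosis from
    non-contrast CT. Computes subject-size indices (total signal index and
    tissue cross-sectional area) directly from axial slices, models the
    scanner's residual beam-hardening artifact from QCT phantom regions of
    known calcium hydroxyapatite density via log-linear calibration
    (CT# = B - A ln(size index)), applies the closed-form subject-size
    correction to cortical Hounsfield units, quantifies histological ground
    truth as the blue-area fraction of Masson-trichrome sections by HSB
    colour thresholding, and evaluates corrected CT numbers as a fibrosis
    biomarker with GEE logistic regression, ROC analysis, paired side tests
    and repeated-measures method correlation. Includes synthetic generators
    (phantom observations, cohorts, CT slice rasters, trichrome images) with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    RNifti,
    lme4,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    withr
Config/testthat/edition: 3
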