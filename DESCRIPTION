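Package: ptxquant
Title: Automated Pneumothorax Quantification from Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation and volumetric quantification of pneumothorax from
    chest CT volumes. Implements per-slice Gaussian smoothing, body-mask
    extraction by fixed Hounsfield-unit thresholding with morphological hole
    filling, adaptive histogram-based estimation of air and lung-parenchyma
    thresholds, 3D connected-component analysis with exclusion of air that is
    continuous with spaces outside the pleural cavity (trachea, bowel,
    exterior), and the relative pneumothorax volume statistic
    V_air / (V_air + V_lung). Ships a synthetic thorax phantom generator with
    ground-truth labels, agreement statistics for method comparison (absolute
    error, Pearson correlation, paired t-test, least-squares trendline), a
    minimal single-series CT DICOM reader, NIfTI I/O, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse,
    yaml
Config/testthat/edition: 3
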