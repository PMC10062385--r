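Package: RamanBreast
Title: Raman Fingerprint Spectroscopy Classification of Breast Tissue
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end workflow for classifying breast tissue (cancer,
    normal, fat) from fingerprint-region Raman spectra. Includes a
    synthetic acquisition and cohort generator with patient-level random
    effects, the full spectral preprocessing chain (accumulation
    averaging, dark subtraction, instrument-response correction,
    wavenumber calibration, BubbleFill baseline removal, standard normal
    variate normalization), a spectral quality-factor gate,
    histology-composition labeling with an exclusion ledger and a
    fat-consistency screen, sparse band selection by an L1-regularized
    linear support vector machine, class-weighted linear SVM
    classification with patient-grouped cross-validation, ROC analysis
    with closest-to-corner operating points, and laser-exposure
    dosimetry arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    signal,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
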