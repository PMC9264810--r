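Package: sersdisc
Title: Chemometric Discrimination of Blood-Derived SERS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for two-class discrimination of
    surface-enhanced Raman (SERS) spectra collected on blood plasma and
    serum.  Provides spectral i/o on plain delimited text, preprocessing
    (resampling to a common 1/cm grid, standard normal variate and area
    normalization, asymmetric-least-squares baseline correction, band
    restriction), from-scratch linear chemometrics (PCA, two-class Fisher
    LDA, NIPALS PLS-DA with VIP variable-importance scores, a linear
    soft-margin SVM), leave-one-out cross-validation with confusion-matrix
    reporting, per-wavenumber Welch/Student t-tests with Benjamini-Hochberg
    false-discovery-rate control and Mann-Whitney AUROC, and a synthetic
    SERS cohort generator with plasma-like and serum-like presets for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    ggplot2,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    e1071,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
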