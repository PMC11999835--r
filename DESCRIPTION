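Package: hsitransfer
Title: Calibration Transfer and Adulteration Mapping for Hyperspectral
    Meat Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sharing spectral discrimination models across
    instruments in visible-range meat authentication. Implements
    piecewise direct standardization (PDS), spectral space
    transformation (SST) and alternating trilinear decomposition (ATLD)
    calibration-transfer estimators with cross-validated hyperparameter
    selection, SPXY sample-set partitioning and standard-set sizing,
    spectral-angle and correlation transfer diagnostics, PLS-DA and
    RBF-SVM species classifiers, and pixel-wise classification of
    hyperspectral cubes into adulteration maps with proportion
    estimates. A synthetic-data module simulates myoglobin-driven meat
    reflectance spectra, master/slave instrument observation and
    spliced-meat hypercubes with ground truth, so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    MASS,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
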