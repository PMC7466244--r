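Package: RamanMinerals
Title: Chemometric Calibration of Mineral Content from Raman Spectra of
    Aqueous Infant Formula
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate calibration toolkit for predicting trace mineral
    concentrations (Ca, Mg, K, Na, Cu, Fe, Zn) in reconstituted infant
    formula from Raman spectra. Implements Whittaker-smoother baseline
    correction (asymmetric least squares and adaptive iteratively
    reweighted penalized least squares), baseline-offset correction and
    Savitzky-Golay first derivatives; PLS1 regression by the NIPALS
    algorithm with venetian-blinds cross-validation and the
    R2/RMSE/bias metric set; informative-variable selection by VIP,
    significance multivariate correlation and Martens' uncertainty test;
    ICP-AES reference arithmetic (standard curves with quality gates,
    dilution-aware quantification, repeatability, percent recovery); and
    a seeded bilinear simulator of the aqueous infant-formula study
    design with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
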