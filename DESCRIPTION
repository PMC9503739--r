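Package: ramanclass
Title: Statistical Classification of SERS Raman Spectra of Genomic DNA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to discriminate surface-enhanced Raman (SERS) spectra of
    genomic DNA from healthy and tumoral cells. Provides a synthetic spectrum
    simulator with Lorentzian peak templates and correlated noise, spectral
    preprocessing (Savitzky-Golay smoothing with raw-edge retention and a
    per-class mean +/- 3 SD decision surface for outlier rejection), a "local"
    classifier built from principal components and logistic regression with a
    probability threshold, a "global" tau-weighted squared-distance
    nearest-mean classifier, 10-fold cross-validated tuning of both thresholds
    by Youden's index, and evaluation via ROC/AUC, Cohen's kappa, and
    joint-classifier agreement tables. Spectra are carried in a
    SummarizedExperiment-derived container.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Preprocessing, Spectrometry, PrincipalComponent
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'evaluation.R'
    'global-model.R'
    'io.R'
    'local-model.R'
    'preprocess.R'
    'ramanclass-package.R'
    'synthetic.R'
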