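Package: shockscale
Title: Shockable Arrhythmia Recognition from Wavelet Scalograms with a
    Hybrid CNN-GRU Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies short (2 s) single-lead ECG fragments into four
    shockable ventricular arrhythmia classes: ventricular flutter,
    ventricular fibrillation, torsade de pointes and high-rate monomorphic
    ventricular tachycardia. Fragments are transformed into Morlet
    continuous-wavelet-transform scalogram images, minority classes are
    balanced by SMOTE interpolation on the raw signals, and the images are
    classified by a lightweight hybrid two-dimensional convolutional /
    gated-recurrent-unit network trained by a built-in single-CPU engine.
    Includes a seeded four-class synthetic ECG generator so the whole
    pipeline runs without any data download, WFDB and CSV readers with
    fixed-window and annotation-centred segmentation, a full evaluation
    suite (confusion matrix, per-class and macro precision, recall,
    specificity, F1, one-vs-rest ROC/AUC, stratified k-fold
    cross-validation, hyperparameter sweeps) and LIME-style superpixel
    explanations of single predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    png,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
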