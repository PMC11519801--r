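Package: sersdc
Title: Deep-Learning Classification of Dendritic-Cell Maturation from
    Single-Cell SERS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for label-free classification of dendritic-cell maturation
    state from single-cell surface-enhanced Raman spectroscopy (SERS) spectra.
    Provides a seeded hierarchical simulator of single-cell SERS datasets
    (band catalogue, class amplitude effects, per-cell scale effects,
    time-courses and mapping grids), plain-text spectra I/O, per-spectrum
    min-max normalisation, per-cell averaging, confidence bands and
    leakage-aware train/validation/test splitting, a one-dimensional
    convolutional neural network (with dense baselines) trained by
    mini-batch SGD with momentum and a plateau learning-rate scheduler,
    evaluation (confusion matrix, ROC/AUC, sensitivity/specificity),
    band-level interpretation (occlusion and weight back-projection
    contributions, tryptophan/carbohydrate band-ratio statistics, channel
    mapping images) and an end-to-end pipeline including time-course
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'sersdc-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'interpret.R'
    'io.R'
    'model.R'
    'pipeline.R'
    'preprocess.R'
    'synthetic.R'
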