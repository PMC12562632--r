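Package: pearHSI
Title: Hyperspectral Prediction of Firmness, Soluble Solids and Maturity in Pears
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-destructive quality assessment of pears from
    near-infrared hyperspectral images (950-1650 nm). Provides white/dark
    reference reflectance calibration, elliptical region-of-interest spectral
    extraction, stratified SPXY calibration/prediction partitioning, a
    multiscale one-dimensional convolutional network with learnable branch
    fusion and an LSTM head for predicting firmness (FI), soluble solid
    content (SSC) and the firmness-soluble-solids ratio (FSR), classical
    chemometric baselines (PLSR, SVR, PCR, PLS-DA, SVM, LDA-RFE),
    RPD-based model evaluation with leakage-free cross-validation, and
    pixel-wise quality-map visualization. A synthetic pear-spectrum
    generator emulating a five-stage maturity study design makes the whole
    pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    e1071,
    mixOmics,
    jsonlite,
    yaml,
    png,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'pearHSI-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'hypercube-io.R'
    'calibration.R'
    'spectrum-table.R'
    'partition.R'
    'nn-config.R'
    'nn-graph.R'
    'baselines.R'
    'evaluation.R'
    'reference-metrics.R'
    'synthetic.R'
    'viz.R'
    'cli.R'
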