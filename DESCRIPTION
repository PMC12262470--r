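Package: nephrosig
Title: Cell-Type-Resolved Nephrotoxicity Signatures from Single-Cell Drug Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying why pseudo-bulk
    transcriptomics masks cell-subtype-mediated drug toxicity in the kidney.
    Provides a seeded synthetic single-cell RNA-seq generator with a 4-type /
    32-subtype kidney hierarchy and a drug-target-toxicity database generator;
    standard single-cell QC, log-normalization and variance-stabilized highly
    variable gene selection; a statistical power simulation that applies
    multiplicative drug effects to responding cells, pseudo-bulks by donor and
    tests per gene; drug2cell-style per-cell composite drug scores from target
    genes; per-cell-type Welch tests with fold changes and FDR correction to
    detect toxicity-susceptible cell types; cross-validated machine-learning
    classification of drug nephrotoxicity from cell-type score features; and a
    bulk differential-expression arm with replicate collapsing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    glmnet,
    e1071,
    randomForest,
    ranger,
    xgboost,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
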