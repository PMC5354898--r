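Package: ppiforest
Title: Protein-Protein Interaction Prediction with PsePSSM Features and
    Rotation Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of protein-protein interactions from
    evolutionary profiles. Parses PSI-BLAST position-specific scoring matrices
    (PSSMs), transforms each variable-length profile into a fixed-length
    pseudo-PSSM descriptor (per-column means plus lag correlation factors),
    concatenates descriptors over ordered protein pairs, and classifies pairs
    with a rotation forest ensemble: decision trees trained on feature
    subspaces rotated by block-diagonal orthonormal matrices obtained from
    principal-axis transforms of bootstrap samples. Includes confusion-matrix
    metrics (accuracy, precision, sensitivity, Matthews correlation
    coefficient), ROC/AUC, stratified k-fold cross-validation, a K-by-L grid
    search, a synthetic profile/pair generator with a tunable interaction
    signal, and a command-line interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
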