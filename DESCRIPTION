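Package: msiRNA
Title: Microsatellite Instability Classification from Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects microsatellite instability (MSI) status from bulk or
    single-cell gene expression matrices. Informative genes are selected with
    a four-stage statistical filter (blacklist and low-expression removal,
    two-sided Wilcoxon rank-sum test, absolute log2 fold change, per-gene
    ROC AUC) followed by dual-model cross-validation ranking; a probability
    emitting support vector machine is trained on SMOTE-balanced data and
    MSI/MSS calls are made at the Youden-index threshold. Single-cell input
    is quality-controlled by detected-gene fraction, dropout-imputed, scored
    per cell and aggregated to a sample-level mean MSI score. A bundled
    simulator generates labeled bulk and single-cell cohorts with planted
    informative genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
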