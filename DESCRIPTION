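Package: pairVote
Title: Rank-Based Gene-Pair Voting Classifiers for Ex Vivo Drug Response
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains and applies k-Top Scoring Pairs (kTSP) classifiers that
    predict ex vivo drug sensitivity of acute myeloid leukemia samples from
    the within-sample ordering of gene pairs, making predictions invariant to
    any monotone (per-sample) transformation of expression and hence robust
    to batch effects. Includes the accompanying drug-sensitivity quantitation
    chain (probit dose-response fitting, normalized AUC on the 0-300 scale,
    DSS1/DSS2/DSS3 and selective DSS), expression normalization (RPKM or
    counts to TPM, protein-coding filter, log2), an imbalance-aware
    benchmarking harness (SMOTE inside cross-validation folds, z-score
    discipline, random-search tuning of SVM, random forest and elastic net
    comparators), evaluation metrics (balanced accuracy, AUROC, one-sided
    Wilcoxon group tests with Benjamini-Hochberg correction, rule-compliance
    profiles, gene recurrence), and a synthetic cohort generator with known
    ground-truth gene pairs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    SummarizedExperiment,
    S4Vectors,
    e1071,
    randomForest,
    glmnet,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
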