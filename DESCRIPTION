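Package: lpiens
Title: Hybrid Ensemble Prediction of lncRNA-Protein Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of lncRNA-protein interactions (LPIs)
    with a hybrid classifier ensemble. Encodes lncRNA and protein sequences
    into fixed-dimension k-mer, k-gap and compositional descriptor vectors,
    selects informative features by AdaBoost forward selection with decision
    stumps, trains three base classifiers (a feed-forward neural network,
    gradient-boosted trees and a soft-margin RBF support vector machine),
    and combines their interaction scores with a fixed weighted average.
    Includes four cross-validation schemes for bipartite link prediction
    (pair-wise, lncRNA cold-start, protein cold-start and fully independent
    nodes), negative sampling, the six standard evaluation metrics, and a
    motif-planted synthetic data generator so the whole pipeline can be
    exercised end-to-end with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    xgboost,
    e1071,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
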