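Package: adrkg
Title: Adverse Drug Reaction Prediction from Knowledge-Graph Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts drug adverse reactions (ADRs) by link prediction on a
    drug/side-effect/target/indication knowledge graph. Each (head, relation,
    tail) triple is treated as a three-token sentence and embedded with a
    CBOW-style softmax context-prediction model; has-side-effect links are
    then scored with a logistic-regression classifier on the difference
    between the ADR and drug embedding vectors. Includes the holdout split
    protocol (10% of drug-indication pairs as test negatives, balanced test
    positives, replicated training negatives), ROC/AUC/precision/recall/F
    evaluation, a synthetic block-model knowledge-graph generator with
    planted cluster signal for benchmarking, and an end-to-end repeated
    experiment and parameter-sweep pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
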