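Package: cbscreen
Title: Narrative-Based Screening for Childbirth-Related PTSD via
    Embedding-Pair Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for screening free-text childbirth narratives for probable
    childbirth-related post-traumatic stress disorder (CB-PTSD). Implements
    PCL-5 questionnaire scoring with a configurable cutoff, narrative
    word-count filtering and class balancing, pairwise data augmentation over
    text embeddings using Hadamard-product features, a feedforward similarity
    network trained with Adam and early stopping, anchor-based classification
    of unseen narratives, hard-label ROC/AUC evaluation with a repeated
    train/test protocol, zero- and few-shot prompt classifiers with a mockable
    chat backend, and a synthetic-data generator so the whole pipeline runs
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    pROC,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
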