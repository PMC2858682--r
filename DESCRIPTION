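Package: cnvclass
Title: Classification of Copy Number Variants as Pathogenic or Benign
    with a Naive Bayes Tree
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates copy number variants (CNVs) with structural and
    functional genomic features (repeat element and segmental duplication
    densities, gene content, evolutionary rates, expression stability,
    mouse knock-out and pathway flags) and classifies them as pathogenic
    (associated with mental retardation) or benign using a hybrid decision
    tree whose leaves hold Naive Bayes models. Includes collinearity
    pruning by variance inflation factor, confusion-matrix and ROC
    evaluation, training-design experiments (class-imbalance sweep,
    training-set selection, leave-one-feature-out contribution, jack-knife
    retraining), a size-matched permutation enrichment test, and a
    synthetic-data generator emulating the class-conditional structure of
    clinical CNV cohorts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
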