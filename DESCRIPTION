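Package: mihclust
Title: Multi-Instance Hierarchical Clustering Learning Systems for
    Gene Function Prediction from Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts gene function from time-course expression profiles by
    building multi-label learning systems over the Gene Ontology.  Per-term
    cliques of significantly co-expressed genes form a de-noised expression
    and annotation system; GO terms are then clustered either by annotation
    up-propagation (gene-number and GO-level constructors) or by multi-instance
    hierarchical clustering under Hausdorff-family bag distances on gene
    expression profiles.  Includes binary-relevance support vector machines
    with class-imbalance loss amplification, a similarity-sum multi-label
    k-nearest-neighbour classifier, a balanced leave-a-percent-out ROC/AUC
    evaluation protocol, and a synthetic data generator with planted
    co-expression modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    withr,
    ape,
    optparse
Config/testthat/edition: 3
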