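Package: pathvote
Title: Diversity-Optimized Pathway Ensemble Classification of Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-class classification of gene expression profiles by an
    ensemble of pathway-restricted support vector machines. Genes are screened
    for differential expression on the training set, each pathway is reduced
    to its differentially expressed members and used as the feature set of one
    SVM base learner, learners are ranked by repeated balanced cross-validation
    accuracy, and the ensemble is assembled by a two-stage diversity-driven
    selection: an incremental prefix search over learners reordered by overall
    disagreement diversity, followed by threshold pruning of low-diversity
    pairs. Survivors are combined by majority vote. Includes a seeded
    synthetic-data generator with pathway-structured class signal, confusion
    matrix metrics, broom-style tidiers, and ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    limma,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
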