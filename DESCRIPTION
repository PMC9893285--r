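Package: celiacpep
Title: Prediction of Celiac Disease Associated Peptides from Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting celiac disease (CD) associated peptides from
    amino-acid sequence. Implements a PQ-density sliding-window statistic
    (maximum proline+glutamine fraction over overlapping windows), discovery and
    scanning of class-exclusive ungapped sequence motifs, amino-acid-composition
    machine-learning classifiers with an 80:20 hold-out plus five-fold
    cross-validation protocol, and a motif-first ensemble predictor in which a
    motif hit asserts a positive call and a composition classifier decides the
    remainder. Includes whole-protein scanning for CD-associated regions,
    exhaustive single-substitution analog design, a seeded synthetic peptide
    generator for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
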