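Package: tcrstack
Title: T-Cell Receptor Repertoire Analytics and Stacked Ensemble Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing T-cell receptor (TCR) repertoires from
    clonotype tables: repertoire input/output in the MiXCR export dialect,
    clonal diversity statistics (Shannon, Gini-Simpson, richness, evenness,
    top clone fraction, clones-to-half), V-J gene usage preferences,
    positional amino-acid composition, CDR3 5-mer motif matrices with
    one-vs-rest differential testing, a deterministic CDR3 descriptor
    encoder with PCA reduction, a two-layer stacked ensemble classifier
    (elastic-net GLM, XGBoost, random forest, neural network grids;
    40 first-layer models, 10 averaged stackers), evaluation harnesses
    with resampling validation, a multinomial read-level repertoire
    simulator, and a synthetic cohort generator with planted group effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
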