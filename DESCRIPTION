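Package: owsum
Title: Interpretable Structure-Odor Classification with Weighted-Sum
    Conditional-Probability Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements OWSum, an interpretable linear classifier that
    predicts a molecule's odor descriptor from binary structural-pattern
    (SMARTS) features.  Per-class feature weights are conditional
    probabilities, optionally tf-idf weighted, and predictions are
    argmax sums of feature influences, so every prediction decomposes
    into named substructure contributions.  Also provides maximum
    common substructure feature-catalog construction over a reference
    corpus, the descriptor-overlap metric for screening semantically
    redundant odor labels, panel-data preprocessing filters, k-fold
    cross-validation with under- and overestimated one-vs-rest ROC AUC
    and Matthews correlation, and a synthetic molecule generator with
    planted structure-odor motifs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
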