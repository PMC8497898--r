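Package: pairsig
Title: Rank-Based Immune lncRNA Pair Prognostic Signatures for Censored Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds prognostic gene-pair signatures from bulk expression data
    using within-sample rank comparisons of immune-related long non-coding
    RNAs (lncRNAs). Implements correlation screening against a curated
    immune-gene list, tumor/normal differential expression, 0-or-1 pair
    indicator matrices with a prevalence filter, univariate Cox screening,
    iterated cross-validated LASSO-Cox selection by occurrence frequency,
    stepwise AIC modelling with AUC-maximized model choice on the
    Kaplan-Meier-based time-dependent ROC, an AIC-minimizing risk-score
    cut-off, and downstream clinical, immune-infiltration and
    chemosensitivity association tests. Includes a synthetic-data generator
    with planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
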