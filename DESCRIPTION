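Package: netresist
Title: Network-Based Molecular Process Models of Chemotherapy Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds segmented molecular process models of drug-resistant
    high-grade serous ovarian cancer and of drug mechanisms of action by
    mapping gene feature sets onto a protein interaction network and
    segmenting the induced subgraph with a molecular complex detection
    (MCODE-style) algorithm. Quantifies drug-disease model interference,
    performs pathway over-representation analysis with Benjamini-Hochberg
    correction, derives a relapse-prognosis transcript panel by bootstrapped
    LASSO logistic regression with optimism-adjusted AUC, and screens
    synthetic-lethal drug-pair interactions with orthology mapping. Includes
    a synthetic-data generator emulating the statistical structure of the
    real inputs so every stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
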