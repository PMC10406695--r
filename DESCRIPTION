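Package: mregnet
Title: Joint Graph Embedding and Network Testing for Morphometric Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Models per-subject morphometric connectivity graphs, built from
    correlated longitudinal volume changes, with a modified Multiple Random
    Eigengraphs (MREG) model: edge probabilities are a sigmoid of a low-rank
    score formed from shared network basis vectors and subject-specific
    loadings. Provides maximum-likelihood joint graph embedding by greedy
    dimension-by-dimension gradient descent on the binary cross-entropy loss,
    confounder-adjusted F-type statistics on the subject-network-structure
    score tensor with max-statistic permutation testing controlling the
    familywise error rate, reference baseline tests (mass-univariate atrophy
    rates, pairwise correlation comparison, a loadings-based classifier), and
    a seeded synthetic cohort generator for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
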