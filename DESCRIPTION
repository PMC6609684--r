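Package: gcsubtypes
Title: Cross-Platform Reproduction of ACRG Gastric Cancer Molecular Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reproduces the four ACRG molecular subtypes of gastric
    adenocarcinoma (MSS/TP53+, MSS/TP53-, MSI and EMT) from gene-level
    expression profiles measured on a second platform. Implements
    cross-platform harmonization (probe collapsing, low-TPM filtering,
    log2 transform, platform intersection), correlation-based filtering of
    signature genes, mean-log2 signature scoring, step-wise subtype
    classification with a Youden-index calibrated TP53 cutoff, a full
    performance and survival evaluation stack, and derivation of a minimal
    gene panel that discriminates the EMT subtype. A synthetic
    paired-platform cohort generator with planted subtypes, cross-platform
    concordance classes, expression dropout and subtype-dependent survival
    makes every stage testable without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    caret,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
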