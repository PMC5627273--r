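Package: interplayr
Title: Interplay Classification for Two-Component Adjuvant Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for factorial transcriptomics experiments that
    compare a two-component combination adjuvant (AS01 = MPL + QS-21) against
    its single components and a PBS control. Fits per-gene cell-means linear
    models with empirical-Bayes variance moderation, calls differentially
    expressed genes with moderated contrast tests, and classifies each gene's
    MPL-by-QS-21 interplay (irrelevance, additivity, synergy, antagonism,
    potentiation, inhibition, emergence) with intersection-union tests that
    combine moderated difference tests and two-one-sided-test equivalence
    tests. Includes principal component analysis of the DEG submatrix with
    rank-based enrichment of interplay categories in component loadings,
    generic hypergeometric over-representation analysis, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    fgsea,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
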