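Package: dcismir
Title: miRNA Expression Deregulation Analysis for DCIS Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking microRNA (miRNA) expression
    deregulation in ductal carcinoma in situ (DCIS) lesions to Oncotype
    DX DCIS recurrence-risk scores. Provides parsing and stratification
    of a clinical cohort table with censored ages, correlation screens
    of small-RNA sequencing count matrices against the continuous risk
    score (Pearson) and patient age (Spearman) with Benjamini-Hochberg
    adjustment, delta-delta-Ct RT-qPCR relative quantification against
    an endogenous control, a composite z-score "miRNA score" that
    discriminates low from intermediate/high risk groups, and a
    negative-binomial synthetic-cohort generator with batch effects and
    planted effects for truth-based validation of every stage.
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
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
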