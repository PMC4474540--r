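Package: pandys
Title: Pan-Cancer Transcription Dysregulation Analysis on Paired Tumor-Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for characterising dysregulated
    transcription across cancer types from paired tumor/normal expression
    cohorts: paired t-test differential expression with Bonferroni control,
    hypergeometric enrichment and depletion of gene categories (transcription
    factors, RNA-binding proteins, lncRNAs, cancer-related genes, mutation
    classes), fold-change amplitude comparison, an RNA-binding-protein
    cascade procedure over protein-protein interaction neighborhoods,
    genetic-versus-epigenetic attribution of expression changes via Spearman
    correlation with copy-number and methylation profiles, tissue-specific
    gene direction analysis, and pathway-restricted hierarchical clustering
    of cancer types.  Includes a fully parameterised synthetic multi-cohort
    generator that plants each of these signals with a machine-readable
    truth ledger, so the whole pipeline is testable without access to
    controlled tumor data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
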