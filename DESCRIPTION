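Package: dgetag
Title: Tag-Based Digital Gene Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of tag-based digital gene expression (DGE/SAGE-style)
    experiments in which each transcript is represented by a 17 nt sequence
    tag anchored at its 3'-most NlaIII (CATG) restriction site. Provides
    in-silico digestion of transcriptomes and genomes into tag catalogues
    with uniqueness classification, exact tag matching and counting into
    tag- and gene-level matrices with tags-per-million normalisation,
    abundance profiling, negative-binomial exact-test differential
    expression with common dispersion and Benjamini-Hochberg FDR control,
    EASE-penalised overrepresentation and ranked-list segmentation
    enrichment, qPCR standard-curve validation, and a synthetic-data
    generator that emulates a paired pre/post training design so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
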