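Package: cadprio
Title: Gene Prioritization at GWAS Loci via SMR/HEIDI Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for prioritizing candidate genes at
    disease-associated loci from GWAS and cis-eQTL summary statistics.
    Implements summary-data Mendelian randomization (the SMR test with the
    Wald-ratio effect estimate), the HEIDI heterogeneity test with a
    weighted-sum-of-chi-square null distribution, a theta similarity metric
    for association patterns, locus discovery and cross-dataset locus
    matching, linkage-disequilibrium computation from reference genotype
    panels, LD-based grouping of gene evidence, and aggregation of
    multi-source evidence including a machine-readable transcription of a
    curated 51-locus coronary artery disease evidence table. A synthetic-data
    generator produces LD-structured panels and paired GWAS/eQTL summary
    statistics under pleiotropy, linkage and null architectures so the whole
    pipeline is testable without external downloads.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
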