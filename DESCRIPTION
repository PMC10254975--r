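Package: methroast
Title: Gene Set Based Integration of DNA Methylome and Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Epigenome-wide association analysis of methylation beta values
    with empirical-Bayes moderated t-statistics, construction of
    direction-by-genomic-region gene sets from significant CpG sites, and
    self-contained rotation gene set testing of expression data against those
    sets. Includes probe/sample quality-control filters, reference-based
    blood cell-type deconvolution, genomic inflation diagnostics,
    hypergeometric over-representation analysis, a synthetic paired
    methylome/transcriptome cohort generator with a known truth ledger, and a
    pipeline orchestrating the full analysis.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
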