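Package: trconverge
Title: Convergent Multi-Regulator ChIP-Seq Binding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Promoter-centric annotation of ChIP-seq peaks, combinatorial
    classification of independent loci co-bound by panels of transcriptional
    regulators together with open-chromatin and histone-mark tracks,
    rank-based cross-dataset concordance of peak lists, interval-shuffle and
    covariate-matched permutation enrichment statistics, and expression
    stratification by regulator count. Ships a synthetic-data generator with
    a ground-truth ledger so every stage of the pipeline is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
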