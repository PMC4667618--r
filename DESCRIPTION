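Package: islandiff
Title: Differential Histone-Mark Island Analysis for Paired ChIP-Seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling and interpreting differential broad histone-mark
    islands (such as H3K27me3) between paired wild-type and mutant ChIP-seq
    libraries. Implements read-level repeat filtering, fragment extension and
    binning, library-size, trimmed-mean, linear-regression and quantile
    normalization, island eligibility and artifact-exclusion filters, fold-change
    classification across developmental stages, promoter/gene-body/intergenic
    annotation, bivalency and co-localization partitioning, expression
    integration, and a summit-centered motif-density permutation test with a
    chi-squared enrichment statistic. A synthetic-data generator with planted
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    limma,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
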