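Package: tadascope
Title: Targeted DamID RNA Polymerase II Occupancy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for Targeted DamID (TaDa) RNA
    polymerase II occupancy profiling. Builds genome-wide GATC fragment
    maps, counts DamID reads mapped on edge to GATC fragments, computes
    per-fragment empirical-Bayes moderated differential statistics between
    a Dam-fusion condition and a Dam-only control, merges significant
    fragments into peaks at the median GATC fragment distance with
    Simes-combined p-values and Benjamini-Hochberg false discovery rates,
    assigns each gene its minimum-FDR overlapping peak, and provides the
    downstream quality-control statistics (TSS distance meta-profiles,
    gene-body occupancy by expression quantile, Fisher enrichment of gene
    classes, multi-list overlap arithmetic) together with a fully
    specified synthetic-data generator with known planted truth.
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
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
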