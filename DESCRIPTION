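Package: tetarget
Title: Transposable-Element Integration Profiles in the Transcriptional Landscape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of transposable-element (TE) integration
    relative to host transcription: gene-anchored insertion metaprofiles around
    transcription start and termination sites (TSS/TTS) and CHH islands,
    expression-rank bin targeting curves, sub-genic insertion enrichment
    statistics, allele-specific knockdown quantification from hybrid read
    counts, and a heuristic classifier of TE targeting strategies (single-peak
    TSS precision, double-peak TSS+TTS, and Pol II-independent). Includes a
    synthetic-data generator for annotated genomes, expression tables, CHH
    islands, allele-count tables and insertion sets under the targeting models,
    so every stage is testable without external downloads.
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
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
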