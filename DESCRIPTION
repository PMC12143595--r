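Package: chromlayers
Title: Layered Multi-Omics Classification of Transcription Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative analysis of pioneer transcription factor activity at
    genomic binding sites. Classifies sites into functional layers -- DNA
    accessibility transitions between conditions, collapsed chromatin states,
    transcription-initiation status and response-element class -- and couples
    the classification to anchored nucleosome-occupancy profiling from
    fragment-size-selected ATAC-seq, transcription start site (CTSS) density
    profiling from CAGE-seq 5' ends, a negative-binomial differential signal
    test with Benjamini-Hochberg correction, a sigmoidal occupancy-to-
    transcription response model, and distance-filtered enhancer-to-gene
    linking. Ships a ground-truthed multi-omics simulator so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
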