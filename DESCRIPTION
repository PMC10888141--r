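Package: netpause
Title: NET-seq Occupancy and Pause-Site Analysis for RNA Polymerase I
    Transcription Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for native elongating transcript sequencing
    (NET-seq) of a single transcription unit such as the yeast rDNA 35S
    precursor. Converts aligned, UMI-tagged reads into per-nucleotide
    last-incorporated-nucleotide occupancy tracks after PCR deduplication,
    normalizes them per library, performs replicate quality control
    (Spearman correlation, sample PCA), tests for position-wise differential
    occupancy between two strains with a per-position Student's t-test,
    compares occupancy distributions in transcribed spacer regions with
    Kolmogorov-Smirnov tests, calls top-quantile pause sites, and summarises
    pause sequence-context differences as a Jensen-Shannon difference logo
    centered on the last incorporated nucleotide. Includes a synthetic
    NET-seq read generator with planted pause motifs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
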