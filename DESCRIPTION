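Package: smrtbs
Title: Targeted Amplicon Bisulfite Sequencing Analysis for Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for highly multiplexed, long-read (CCS-level)
    targeted amplicon bisulfite sequencing. Provides barcode demultiplexing
    with bounded edit distance, bisulfite-aware three-letter alignment of
    reads to amplicon references, per-read conversion-rate and clonal
    PCR-artifact filtering, depth-gated per-CpG methylation quantitation,
    replicate reproducibility statistics, equimolar pooling calculations,
    CpG-island coverage analysis, and a read simulator that generates
    barcoded bisulfite amplicon reads with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
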