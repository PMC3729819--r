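Package: dsbscape
Title: Meiotic DSB Hotspot Calling, Consensus Scanning and Chromosomal
    Landscapes for SSDS Fragment Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of single-stranded DNA sequencing (SSDS) fragment data
    from meiotic double-strand-break (DSB) mapping experiments: per-end
    quality filtering and per-locus duplicate capping of ssDNA fragments,
    replicate pooling, Poisson local-background hotspot calling with
    Benjamini-Hochberg control, exhaustive no-mismatch scanning for gapped
    IUPAC consensus motifs (the Gal4 consensus CGG-N11-CCG), central-window
    overlap classification of hotspots against reference hotspot sets,
    H3K4me3 peaks, transcription start sites and motif sites,
    motif-centered coverage profiles, 1-Mb normalized in-hotspot coverage
    landscapes with a subtelomeric depletion statistic, and the
    pseudoautosomal-region cluster fragment fraction. Includes a
    synthetic-data generator that emulates the statistical structure of
    SSDS experiments, so the whole pipeline is testable end to end against
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
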