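Package: leakyscan
Title: 5' UTR Length, Alternative Transcription Start Sites, and Leaky
    Ribosome Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links 5' untranslated region (UTR) length to alternative
    N-terminal protein isoform production. Calls single-nucleotide
    transcription start sites (CTSS) from CAGE alignments, normalizes them
    to tags per million, and classifies alternative promoters against
    representative start codons; annotates spliced 5' UTR lengths from GTF
    transcript models under three representative-transcript strategies
    (highest expressed, MANE Select, longest CDS); relates UTR length to
    N-terminal truncation frequency using start-site ribosome-profiling
    initiation calls; and screens ClinVar-style variant tables for 5' UTR
    indels, computing signed UTR-length changes from genomic coordinates
    and HGVS c.-notation and predicting leaky-scanning consequences
    relative to the 40 nt short-UTR regime. Ships a seeded synthetic-data
    generator with ground-truth manifests so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
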