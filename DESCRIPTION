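Package: covcap
Title: Coverage-Capped Downsampling of Coordinate-Sorted Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Enforces a strict per-position coverage cap on coordinate-sorted
    SAM/BAM alignment files using a single-pass sweep-line algorithm with
    seeded random read priorities, so that at every reference position at most
    N reads are retained and the retained reads are an unbiased, reproducible
    random sample of those covering the position. Provides a single-pass mode
    for long single-end reads, a two-pass mode that preserves template (mate
    pair) integrity for paired-end data, and an index-based batched-fetching
    strategy that samples reads window by window. Includes per-position depth
    computation for cap verification and a deterministic simulator producing
    synthetic references and alignments for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
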