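Package: igqc
Title: Assembly Quality Assessment for Immunoglobulin Loci from Long-Read
    Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates the accuracy and completeness of genome assemblies
    over immunoglobulin (IGH/IGK/IGL) loci using alignments of accurate
    long reads. Computes per-read mismatch statistics, per-position
    read-oriented and basepair-oriented support metrics, detects and
    classifies breaks in read coverage, reports per-gene support, calls
    per-locus quality categories and aggregates them across species.
    Includes a synthetic diploid-locus simulator that injects known
    assembly defects (missing segments, inversions with N-gaps) with
    machine-readable truth, so every detector is verifiable offline, and
    diagnostic visualizations of coverage, mapping quality and support.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    ggplot2,
    jsonlite,
    methods,
    patchwork,
    rlang,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
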