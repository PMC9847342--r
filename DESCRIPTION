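Package: ulscaf
Title: Ultra-Long Read Contig Scaffolding and Assembly Repeat Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Scaffolds genome assembly contigs with ultra-long nanopore reads by
    turning read-to-contig alignments (PAF) into a contig-end contact graph,
    filtering it by supporting-read count and reciprocal-best linkage, simplifying
    it (branch removal, weakest-link cycle breaking) and emitting ordered,
    oriented scaffolds with median-based gap estimates as FASTA, GFA 1.0 and
    AGP 2.1. Also provides assembly diagnostics built on tandem-repeat arrays:
    telomere and centromere detection, classification of contig ends by AT
    dinucleotide arrays, Nx statistics, kernel-density Ks peak detection with
    ratio-based whole-genome-duplication dating, and TPM expression
    normalisation. A seeded synthetic-genome and ultra-long-read simulator with
    full ground truth makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
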