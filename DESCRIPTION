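Package: telotape
Title: Telomere Length Profiling from Nanopore Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects noisy telomeric repeat tracts in basecalled nanopore
    reads with a wraparound dynamic-programming repeat finder, filters reads
    by terminal telomere structure, calls per-read telomere length with a
    segment-concatenation rule, anchors reads to chromosome arms and alleles
    against a pangenome of telomere-to-telomere chromosome ends, and computes
    cohort-level telomere statistics including shortening-rate regression and
    telomere-maintenance-mechanism classification by length-distribution
    dispersion. Includes a truth-known read simulator with virtual
    restriction digestion for validating the whole stack.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    ggplot2,
    yaml,
    stats,
    tools,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: minimap2 (optional, for the bundled alignment wrapper)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
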