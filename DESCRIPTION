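Package: radipr
Title: RNA-Chromatin Interaction Mapping from RADICL-seq and RADIP Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end processing of proximity-ligation RNA-chromatin
    interaction libraries of the RADICL-seq / RADIP family, in which each
    sequencing read is a chimera of an RNA tag and a DNA tag joined by an
    internal bridge adaptor. Provides chimeric read deconvolution, strand-aware
    annotation of tag pairs to genes and fixed-width genomic bins, a per-RNA
    zero-truncated negative-binomial background model for calling significant
    interactions, TMM-normalised negative-binomial differential interaction
    testing between immunoprecipitated and input libraries, summary analytics
    (distance classes, bin-bin contact matrices, peak-centred meta-profiles,
    saturation curves, Monte-Carlo chi-square sample comparison), and a
    synthetic-data generator that emits FASTQ, SAM and truth tables so the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    Matrix,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    optparse
Config/testthat/edition: 3
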