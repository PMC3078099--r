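Package: polyamp
Title: Barcoded Amplicon Sequencing of Polyploids: Demultiplexing, Allele
    Calling and Read-Depth Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooled amplicon sequencing of polyploid individuals
    with checksum-protected sample barcodes. Provides the 64-word barcode
    vocabulary with single-substitution error detection, read demultiplexing
    by primer matching, 454-style quality control (end trimming, N-masking,
    length filtering), per-sample allele calling for homeologous loci under a
    minimum-difference/consistency rule, partitioning of alleles into gene
    copies with fixed-difference and shared-polymorphism diagnostics, indel
    coding for distance analyses, PCR-chimera detection by the
    minority-frequency/split-parent rule, the inverse coupon-collector model
    of the read depth needed to observe all alleles (analytic and Monte
    Carlo), origin-forced copy-ratio regression, and a synthetic read
    simulator with full truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
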