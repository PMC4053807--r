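Package: areclip
Title: Downstream Analysis of PAR-CLIP Binding Sites for AU-Rich Element
    Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream computational analysis of PAR-CLIP
    binding-site (PARalyzer cluster) tables from AU-rich element (ARE)
    binding proteins such as ZFP36 and ELAVL1: annotation of clusters to
    transcript regions, per-nucleotide motif signal-to-noise (SNR)
    enrichment, calibration of SNR against in-vitro dissociation constants
    by a power-law fit with in-silico spacer-disruption scans, Spearman
    partial-correlation decomposition of binding/expression relations
    (residual, recursive and matrix-inversion routes), permutation-based
    positional and cross-RBP proximity statistics, and a synthetic-data
    generator that emulates the statistical structure these analyses
    assume so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
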