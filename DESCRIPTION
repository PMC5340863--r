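Package: subotu
Title: Per-Sample Sub-OTU Denoising of Amplicon Sequences by Greedy
    Error Subtraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers exact amplicon sequence variants (sub-OTUs) from
    demultiplexed 16S rRNA gene reads by greedy, abundance-ordered
    subtraction of predicted error-derived reads, using an upper-bound
    per-Hamming-distance error profile. Each sample is denoised
    independently, so feature tables from different sequencing runs can
    be merged on exact sequence identity. Includes the surrounding
    pipeline stages (trimming, dereplication with singleton removal,
    reference-based artifact screening, center-star multiple sequence
    alignment, de novo two-parent chimera detection), exact-sequence
    feature tables with BIOM/TSV input and output, rarefaction, and a
    benchmarking toolkit (community and read simulator, ground-truth
    scoring, technical-replicate stability curves, UPGMA trees and
    unweighted UniFrac distances).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    biomformat,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
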