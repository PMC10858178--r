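Package: proviscan
Title: Split-Read Discovery of Provirus Integration Sites and APOBEC3
    Hypermutation Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates new provirus (retroviral transgene) integration sites in
    a host genome from whole-genome paired-end sequencing using split
    (chimeric) read evidence: quality trimming with the 3' partial-sum rule,
    seed-and-chain split alignment against the combined host plus provirus
    reference, extraction of uniquely mapped trans splits, discard rules for
    singular splits without terminal-UTR support and for unplaced scaffolds,
    single-linkage breakpoint clustering, and depth/breadth coverage
    summaries. Also quantifies cytidine-deaminase (APOBEC3) hypermutation in
    cloned amplicon sequences via global alignment, substitution spectra and
    per-mouse summaries. Includes a seeded synthetic-data generator (multi
    contig references, target-site-duplicated insertions, paired-end reads
    with base-call errors and 3'-decaying qualities, mutated amplicon clones)
    with machine-readable truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
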