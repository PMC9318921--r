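Package: synregulon
Title: Discovery and Genome-Wide Mapping of CodY-Like Regulons in
    Synergistetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to infer a CodY-like regulon in Gram-negative
    Synergistetes from genome sequence alone: a domain-architecture screen
    that nominates GAF + winged helix-turn-helix proteins from HMMER
    per-domain tables, extraction of operon-leader promoter sets from
    FASTA/GFF3 genomes, discovery of spaced AT-rich palindromic (dyad)
    binding motifs by exhaustive arm/spacer enumeration with binomial
    significance and ZOOPS expectation-maximization refinement, genome-wide
    scanning with degenerate consensus patterns and position weight
    matrices with exact dynamic-programming p-values, promoter
    classification by canonical CodY box versus extended palindrome
    content, and log2(N+1) functional-category enrichment matrices.
    Includes seeded synthetic-data generators (background promoters at a
    target GC, planted dyads with truth tables, operon-structured genomes,
    domain-hit fixtures, binding-probe variant series) so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    optparse
Config/testthat/edition: 3
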