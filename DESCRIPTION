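Package: hotspotr
Title: Somatic Point-Mutation Hot-Spot Analysis for Hypermutated Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects recurrent somatic point-mutation hot spots in hypermutated
    tumor cohorts (such as microsatellite-unstable colorectal cancer) from
    per-tumor SNV call sets. Implements the full analysis path: quality,
    variant-class, capture-region and germline/population-frequency filtering;
    codon-level consequence annotation against CDS gene models; clustering of
    non-synonymous and splice-site mutations into same-codon, adjacent-codon
    and splice-flank hot spots; discovery/validation cohort frequency
    statistics; and a mutation-type-stratified permutation test that
    redistributes the 18 CpG-aware substitution types across exome capture
    regions to assess exome-wide hot-spot excess. A self-contained synthetic
    cohort generator with planted hot spots supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
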