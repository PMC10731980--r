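Package: mamutspec
Title: Heritable Mutation Detection and Spectrum Analysis for Mutation-Accumulation Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-variant-calling analysis of heritable de novo mutations in
    diploid mutation-accumulation (MA) line cohorts. Provides locus-level
    quality filtering and singleton (unique-site) selection to separate
    line-private de novo mutations from shared germline variants,
    zygosity-weighted per-site mutation-rate estimation, the directed
    12-class substitution spectrum with transition/transversion statistics,
    flanking-sequence context matrices around mutated sites, insertion/deletion
    size and slippage-context (homopolymer and tandem-repeat adjacency)
    classification, genomic-region annotation from GFF3 with SIFT-based
    deleteriousness calls, and one-way ANOVA/Tukey group comparisons with
    compact letter displays. A synthetic MA-cohort simulator with a planted
    ground truth makes every stage of the pipeline testable without access
    to a sequencing study's raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
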