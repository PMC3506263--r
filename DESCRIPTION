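Package: piRNAhybrids
Title: piRNA Pathway Collapse Diagnostics for Interspecific Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to diagnose piRNA-pathway dysfunction from ovarian
    small-RNA and mRNA sequencing of interspecific hybrids and their
    parental species. Implements transposable-element (TE) expression
    quantification against consensus sequences with dual-parent
    derepression calling, small-RNA size-class and antisense-fraction
    profiling, the ping-pong amplification fraction (exact 10-nt 5'-5'
    overlap statistic), piRNA-cluster activity under three multimapper
    counting schemes with additive-inheritance classification, a
    comparative-statistics layer (G-test, chi-square, Wilcoxon, pooled t,
    Pearson and partial correlations with a permutation null), and a
    fully seeded synthetic-data generator producing two diverged parental
    genomes, annotated TE insertions and piRNA clusters, small-RNA
    libraries with tunable ping-pong pairing, and negative-binomial mRNA
    count tables with planted fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'clusters.R'
    'expression.R'
    'io.R'
    'mapping.R'
    'pingpong.R'
    'pipeline.R'
    'profile.R'
    'simulate.R'
    'stats.R'
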