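Package: TFloopNet
Title: Hierarchy and Dynamics of Transcription Factor Cooperation from
    Chromatin Loops, ChIP-Seq Co-Localization and Protein Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates three views of transcription factor (TF) cooperation
    into a single fused TF network and characterizes its organisation.
    Enhancer-promoter chromatin loops are derived from ChIA-PET style contact
    lists annotated with chromatin states; linear-genome co-binding is scored
    with an interval-proximity significance statistic over ChIP-Seq peak sets,
    yielding an asymmetric TF-by-TF similarity matrix; motif occupancy of loop
    anchors (exact PWM-scan p-values and rank-based promoter enrichment)
    selects the TFs whose protein-protein interactions form a 3D adjacency.
    The 1D and 3D matrices are merged by similarity network fusion, and the
    fused network is analysed for hierarchy (simulated annealing on a
    permutation-corrected hierarchy score), overlapping communities
    (cohesiveness-greedy growth), maximal cliques (Bron-Kerbosch),
    cross-cell-line clique dynamics, clique-regulated genes, expression
    coherence, and clique-by-gene biclusters via sparse factor analysis.
    A synthetic-fixture generator with planted ground truth supports
    desk-scale validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
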