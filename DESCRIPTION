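Package: metadecay
Title: Motif-Integrated Analysis of m6A Methylation, AU-Rich Elements and
    mRNA Decay in CD8+ T Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects composite ARE-flanking m6A sites by integrating
    crosslink-based (miCLIP-style) and conversion-based (GLORI-style) m6A
    signals with pentamer motif maps of 3'UTRs, estimates mRNA half-lives
    from metabolic-labelling (SLAM-seq-style) conversion time courses by
    exponential decay fitting, clusters motif-partitioned 3'UTR count
    matrices, compares half-life distributions with Kolmogorov-Smirnov
    statistics stratified by ARE-RRACH distance, and classifies unstable
    versus stable transcripts with a random-forest model equipped with
    conditional permutation importance. A seed-deterministic synthetic-data
    generator with a ground-truth manifest stands in for deposited
    sequencing data and drives the end-to-end analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    Biostrings,
    minpack.lm,
    ranger,
    mclust,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    pROC
Config/testthat/edition: 3
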