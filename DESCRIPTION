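Package: lncdev
Title: Developmental lncRNA Discovery, Expression and Synteny Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of a developmental
    transcriptome assembled without biological replicates, modelled on
    compact teleost genomes. Implements an evidence-based long non-coding
    RNA (lncRNA) classification cascade (homology, ORF length, non-coding
    potential, positional filtering, CAGE support), replicate-free
    differential expression using a conditional negative-binomial exact
    test with housekeeping-inferred common dispersion and maternal versus
    embryonic stage calling, exon-level sequence conservation scoring from
    multi-genome alignment blocks with a shuffle background, microsynteny
    detection for intergenic lncRNAs with a randomisation null,
    transposable-element association statistics, and Fisher-exact GO
    enrichment. A synthetic-data generator with planted ground truth
    exercises every stage end-to-end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
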