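Package: pol3prox
Title: Occupancy Profiling and Feature-Proximity Enrichment for Pol III-Transcribed Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Strand-aware metagene occupancy profiling of positional tag
    tracks (ChIP-exo style forward/reverse counts) over RNA polymerase
    III-transcribed genes, with a gene-end confound filter and ORF-density
    profiles; a distance-binned feature-proximity enrichment statistic
    around replication origins and TAD boundaries with a
    proximal-versus-distal two-tailed t-test; the ChIP-qPCR fold
    enrichment method (double-delta-Ct with a subtelomeric control
    region and mock normalization); library-size normalization and log2
    comparison of tRNA abundance count tables; and a synthetic-genome
    simulator with planted peaks, co-localization, fold enrichments and
    abundances so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
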