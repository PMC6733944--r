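# pol3prox

Genome-scale occupancy and proximity analysis for RNA polymerase
III-transcribed genes, built on Bioconductor containers (`Seqinfo`,
`GRanges`, S4 result classes).

tRNA genes are short, heavily transcribed pol III loci whose chromatin
questions reduce to a handful of computations on positional ChIP
signal. `pol3prox` implements them as a tested, reusable pipeline:

* **Strand-aware metagene profiling** of ChIP-exo-style tag tracks
  (sparse per-position forward/reverse counts): mean collapsed signal at
  every gene-oriented offset around the TSS or TTS, per-gene heatmap
  matrices with rescaled gene bodies, and windowed mean occupancies for
  correlation analyses (`pearsonR`).
* **Confound handling** for the crowded neighborhoods tRNA genes live
  in: a pol II gene-end filter (drop tRNAs with an ORF end within a
  window on both, or either, side) and ORF-density profiles (proximal
  ends per 100-bp window around the tRNA body, same strand by default).
* **Feature-proximity enrichment** around replication origins and TAD
  boundaries: points (TSSs with weight 1, or tag positions weighted by
  count) aggregated into signed-distance bins per feature, curves
  normalized by total point counts, and a proximal-versus-distal
  two-tailed Student's t-test. With per-feature proximal mean `P_f` and
  distal mean `D_f`,

  `t = (mean(P) - mean(D)) / (s_pooled * sqrt(1/n + 1/n))`, `n` = feature count,

  with proximal bins overlapping `[-h, +h)` (default h = 0.5 kb at TAD
  boundaries, 1.5 kb at origins) and distal the bin pair at the ± distal
  offset (2.5 kb / 5 kb).
* **ChIP-qPCR fold enrichment** (double-delta-Ct against the TelVIR
  subtelomeric control, input-corrected, mock-normalized):

  `FE = E^-(dCt_IP - dCt_input) / E^-(dCt_mock - dCt_input)`,
  `dCt_s = Ct_s(gene) - Ct_s(TelVIR)`,

  plus replicate aggregation with scatter, condition ratios, band-ratio
  normalization and the shared replicate t-test.
* **Count-table comparison**: counts-per-million normalization, log2
  with pseudocount, per-row fold changes.
* **A synthetic-data generator** planting every truth the pipeline
  estimates — peak offset, co-localization fraction, fold enrichments,
  abundances — so calibration, power and parameter recovery are
  testable without any external download.

## A worked example

```r
library(pol3prox)

cfg <- simulationConfig(seed = 7, colocalizationFraction = 0.5)
sim <- simulateGenome(cfg)             # genome + genes + origins/TADs
track <- simulateTagTrack(sim$genes, cfg)
trna <- sim$genes[S4Vectors::mcols(sim$genes)$gene_class == "tRNA"]

prof <- computeProfile(track, trna, flank = 300)
prof
#> OccupancyProfile (TSS-anchored): offsets -300..300, 150 genes averaged
profileOffsets(prof)[which.max(profileValues(prof))]
#> [1] -9

report <- runProximityAnalysis(sim$genes, sim$features, track = track)
report$tad_boundaries$tests
#>   signal     t df        p n_features
#> 1   trna  8.43 78 1.36e-12         40
#> 2    orf -1.52 78 1.32e-01         40
#> 3   tags  6.68 78 3.14e-09         40

ct <- simulateCt(simulationConfig(seed = 7, ctNoiseSd = 0))
foldEnrichment(ct, "tS1", "wt", 1)
#> [1] 8
```

Reading the numbers: the metagene peak lands at −9 bp, within sampling
error of the planted −10 bp offset upstream of the TSS. Half the tRNAs
were planted within 500 bp of TAD boundaries, and the proximity test
finds them (p = 1.4e-12) while the ORF control stays flat
(p = 0.13); the tag track, peaked on those same tRNAs, is enriched too.
The noise-free Ct table inverts exactly to the planted 8-fold
enrichment.

A command-line entry point wraps the same functions:

```sh
Rscript inst/cli/pol3prox.R simulate --config sim.yaml --out fixtures/
Rscript inst/cli/pol3prox.R proximity --genes fixtures/genes.tsv \
    --chrom-sizes fixtures/chrom.sizes --features fixtures/origins.tsv \
    --features fixtures/tad_boundaries.tsv --track fixtures/tags.tsv \
    --out report/
```

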