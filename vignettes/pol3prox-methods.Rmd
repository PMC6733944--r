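---
title: "Methods: occupancy profiling and feature-proximity enrichment for pol III genes"
author: "pol3prox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy profiling and feature-proximity enrichment for pol III genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pol3prox)
```

## The scientific setting

RNA polymerase III transcribes the tRNA genes, short (~100 bp) and
intensely transcribed loci scattered through the yeast genome. Several
questions about their chromatin regulation reduce to a small set of
genome-scale computations on positional ChIP signal:

1. **Where does a factor sit on these genes?** ChIP-exo produces, after
   processing, near-base-pair tag counts per chromosomal position in a
   forward and a reverse channel. Averaging the collapsed (summed)
   counts across all tRNA genes, aligned at the TSS and read in gene
   orientation, gives a *metagene occupancy profile*; a sharp mode a few
   bp upstream of the TSS (around −10 bp, between the TFIIIB footprint
   at −30 bp and box A at +20 bp) is the kind of feature this profile
   resolves.
2. **Is the signal on the tRNA gene or bleeding over from a neighbor?**
   tRNA genes often sit close to pol II-transcribed ORF ends. The
   package therefore provides a *gene-end confound filter* (drop tRNAs
   with an ORF end within a window on both — or either — side) and an
   *ORF-density profile* (ORF proximal-end counts in 100-bp windows
   around the tRNA body, same strand only by default) to quantify that
   neighborhood.
3. **Do tRNA genes (or factor binding) cluster near replication origins
   and TAD boundaries?** Points (TSSs, or tag positions weighted by
   count) are aggregated into signed-distance bins around each feature;
   per-feature means of feature-proximal bins are compared with
   feature-distal bins by a two-tailed unpaired Student's t-test.
4. **How much factor is at one locus?** ChIP-qPCR with the fold
   enrichment method: Ct values from IP and mock are normalized first
   against the subtelomeric TelVIR control region, then against input,
   and exponentiated with the amplification efficiency.
5. **Did abundances change?** Count tables are library-size normalized
   (counts per million), log2-transformed with a pseudocount, and
   compared per row.

Every stage is exercised end to end on synthetic genomes with planted
signal, so the statistical behaviour of the pipeline (calibration,
power, recovery of planted parameters) is itself tested.

## Coordinate and orientation conventions

Internally everything lives in Bioconductor containers: a
`GenomeInfoDb::Seqinfo` for the genome, `GRanges` for genes and point
features, and an S4 `TagTrack` for sparse positional counts.
Coordinates are therefore **1-based and closed**, the Bioconductor
convention; BED input/output is converted by `rtracklayer`, and
tab-delimited gene/tag tables are documented as 1-based and stored
unchanged (a flag switches the tag-table dialect). The TSS of a `+`
gene is its `start`, of a `-` gene its `end`.

Two different orientation rules coexist deliberately:

* **Metagene quantities are gene-oriented.** "Upstream" at offset −k
  means k bp before the TSS in the direction of transcription;
  minus-strand genes are read right to left. Offset 0 is the anchor
  base, so a `[-flank, +flank]` profile has `2*flank + 1` positions.
* **Proximity quantities are genome-oriented.** Origins and TAD
  boundaries are unstranded reference points; the signed distance is
  `point − feature` in genome coordinates and enrichment curves are
  aggregated without strand flipping. Interval-shaped feature sources
  are collapsed to midpoints (`floor((start + end) / 2)`) before use.

Bins are half-open `[lo, hi)` tiling `[-maxDist, +maxDist)`; distance 0
falls in the first non-negative bin. "Within d" subsetting
(`genesWithin`) is closed (`<=`), measured from the TSS by default with
a nearest-edge mode as a flag, since published counts of "genes within
1 kb" do not state the anchor.

## The proximity statistic

`relativeBinCounts()` adds each point's weight to the bin containing
its signed distance from *every* feature within `maxDist` on the same
chromosome — aggregation, not nearest-feature assignment. This makes
mass conservation checkable (with well-separated features the matrix
total equals the total point weight) and matches the additive reading
of "aggregating counts in genomic bins". Curves are per-bin means
across features, divided by a recorded normalizer (the total TSS count
of the aggregated gene set — e.g. all tRNAs vs all ORFs — or total tags
in millions) so signal and control curves share a scale.

`proximalDistalTest()` reads "the resulting vectors" as **per-feature
vectors**: one proximal mean and one distal mean per feature, so the
sampling unit is the feature and n is the feature count. (A `bin_means`
mode using the curve values instead is available but not default; the
per-feature reading gives a defensible sampling unit.) Proximal bins
are those overlapping `[-h, +h)`; distal bins are the single bin pair
containing the ± distal offset — the stated offsets name positions, not
ranges — with a `beyond` mode widening to all bins outside the radius.
Defaults per feature type: TAD boundaries ±0.5 kb proximal / ±2.5 kb
distal (narrow enrichment range); replication origins ±1.5 kb proximal
/ ±5 kb distal (broader range); 1000-bp bins for TSS signals, 100-bp
bins for tag tracks.

The test itself is the two-tailed unpaired Student's t-test with pooled
variance (Welch as a flag), shared with `replicateTTest()` for qPCR
replicates. Degenerate inputs are defined before dispatch: zero
variance in both groups with equal means is "no difference" (t = 0,
p = 1); zero variance with unequal means is an error, not a number.

## The fold enrichment method

With `dCt_s = Ct_s(gene) − Ct_s(TelVIR)`:

`FE = E^−(dCt_IP − dCt_input) / E^−(dCt_mock − dCt_input)`

The mock normalization is a division on the multiplicative scale (the
standard exponentiated ΔΔCt reading of "normalized against the mock"),
applied per replicate, and replicates are aggregated by arithmetic mean
with min/max scatter (SD also reported). Amplification efficiency
defaults to 2.0 (perfect doubling) with an override, since efficiencies
are rarely reported alongside Ct tables. Algebraically the input terms
cancel, but they are kept in the computation so tables with informative
inputs are validated the same way. Estimates with p > 0.05 against a
named reference condition are flagged non-significant, mirroring the
dot convention of qPCR figures.

For abundance tables, counts-per-million with pseudocount 1 is the
normalization; this is a stated stand-in for unpublished pipeline
details of hybridization-based tRNA sequencing, not an inference of
what those were.

## What the simulator emulates

`simulationConfig()` defaults describe a ~1/10-scale budding-yeast
study, chosen once as the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| genome | 4 chromosomes × 300 kb | ~1/10 of the 12-Mb yeast genome |
| tRNA genes | 150, lengths 70–120 bp | enough genes for stable metagene averages; real tRNA genes average ~100 bp |
| ORFs | 300, lengths 500–2000 bp | ~33% genome occupancy keeps uniform non-overlapping placement tractable; yeast itself is denser (~70% coding), but ORF count does not enter the tRNA statistics |
| origins / TAD boundaries | 40 each | ~1/10 of confirmed yeast origins; gives n = 40 features for the t-test |
| background | 0.05 tags/bp Poisson | sparse genome-wide floor typical of processed ChIP-exo |
| peak | mean 100 tags/gene at −10 ± 5 bp (SD) | ChIP-exo resolves near-base-pair peaks; 5 bp keeps the planted mode single-base resolvable at realistic amplitudes (a 15-bp spread would let the profile argmax wander several bp from Poisson noise alone) |
| Ct noise | 0.2 cycles | typical qPCR technical scatter |
| co-localization | fraction 0, window 500 bp | null by default |

The co-localization plant places `round(fraction × n_trna)` tRNA TSSs
uniformly within the window around a feature; the **remaining tRNAs are
placed uniformly with no exclusion zone**. An exclusion zone would
plant *depletion* at fraction 0 and destroy null calibration, so the
planted count is a floor, not an exact total. Ct tables are constructed
to invert exactly under the fold-enrichment formula at zero noise;
count tables are multinomial draws from the planted abundance profile.

Features of real data deliberately *not* emulated: mappability and
copy-number artifacts, crosslinking sequence bias, strand-asymmetric
exonuclease footprints, chromosome-scale covariates (centromeres,
telomeres), and replication-timing structure. Passing tests therefore
demonstrate correctness of the computations and the statistical
behaviour of the methods under clean sampling noise — not robustness to
every artifact of deposited datasets.

## Numerical and design choices

* Genes whose profile window crosses a chromosome end are **excluded**
  from profiles and heatmaps (equal-length rows) but **truncated** for
  single-gene windowed means; both are logged via `message()`.
* Heatmap gene bodies are rescaled by mean pooling into contiguous
  chunks; genes shorter than the bin count are linearly interpolated
  (logged). Row ordering (descending row sum) is presentation only.
* ORF-density windows assign an ORF by its proximal end, not by
  overlap; ORFs overlapping the tRNA body fall in no window.
* Duplicate tag-table rows are summed with a message (tolerant of split
  depositions); structurally invalid rows are rejected with the line
  number, never repaired silently.
* Tag-track points enter proximity binning as collapsed per-position
  weights, matching the summed-channel form of the processed data.
* All simulation randomness flows through one master seed with fixed
  per-component offsets (genome +0, track +1, Ct +2, counts +3), so
  components regenerate independently and every generator is a pure
  function of its config.
* The `runCli()` dispatcher (with the thin `inst/cli/pol3prox.R`
  script) covers simulate / metagene / proximity / qpcr / counts /
  convert; unknown keys are rejected by name and each run writes a
  manifest from which the results are regenerable.

## Problem sizes used in validation

The shipped validation suite measures, at the default study conditions:
type-I error of the proximity test over 1000 simulated null genomes
(expected ≈ 0.05); detection power over 100 genomes with half the tRNAs
planted within 500 bp of TAD boundaries (p < 0.01 expected in ≥ 90%);
metagene argmax recovery of the −10 bp plant over 50 tracks (±2 bp);
exact zero-noise qPCR inversion and mean recovery within 15% at
0.2-cycle noise over 200 tables; plus exact brute-force equivalence for
the binning, filtering and subsetting engines on randomized fixtures.
`scripts/acceptance.R` recomputes these quantities from scratch for any
seed. ORF placement is switched off (`nOrf = 0`) in the calibration,
power and peak replicates since ORFs do not enter those statistics and
their placement dominates runtime.

## Known limitations

* The t-test treats features as independent; features closer than twice
  `maxDist` share points, and heavy feature crowding would call for a
  permutation framework, which is intentionally out of scope (the
  permutation test appears only as a validation oracle).
* Profiles average raw tag counts by default; per-million scaling is a
  flag. Published profiles do not always state which was used.
* The qPCR machinery assumes one amplification efficiency for all
  amplicons; no standard-curve estimation is provided.
* No BAM/FASTQ handling: the pipeline starts from processed positional
  counts, and no read-level simulation is attempted.

## A worked miniature

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 7, colocalizationFraction = 0.5)
sim <- simulateGenome(cfg)
track <- simulateTagTrack(sim$genes, cfg)
trna <- sim$genes[S4Vectors::mcols(sim$genes)$gene_class == "tRNA"]

prof <- computeProfile(track, trna, flank = 300)
profileOffsets(prof)[which.max(profileValues(prof))]  # ~ -10

report <- runProximityAnalysis(sim$genes, sim$features, track = track)
report$tad_boundaries$tests  # planted tRNA co-localization: tiny p
```
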