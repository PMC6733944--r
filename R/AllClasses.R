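#' @import methods
#' @importClassesFrom GenomeInfoDb Seqinfo
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Sparse positional tag counts with forward and reverse channels
#'
#' A `TagTrack` stores ChIP-exo-style processed signal: for every occupied
#' chromosomal position, a forward-strand and a reverse-strand tag count,
#' plus their sum (the collapsed channel most analyses consume). Positions
#' are 1-based and must lie within the bounds of the accompanying
#' [GenomeInfoDb::Seqinfo]. The representation is sparse: positions with no
#' tags are absent and read as zero.
#'
#' @slot data data.frame with columns `chrom`, `pos`, `fwd`, `rev`, `total`,
#'   sorted by (`chrom`, `pos`), one row per occupied position.
#' @slot seqinfo the genome the positions refer to.
#' @export
setClass("TagTrack", slots = c(data = "data.frame", seqinfo = "Seqinfo"))

setValidity("TagTrack", function(object) {
  d <- object@data
  need <- c("chrom", "pos", "fwd", "rev", "total")
  if (!all(need %in% names(d)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (nrow(d) == 0L) return(TRUE)
  if (anyDuplicated(d[c("chrom", "pos")]))
    return("duplicate (chrom, pos) rows")
  if (any(d$fwd < 0) || any(d$rev < 0)) return("negative tag counts")
  if (any(abs(d$total - (d$fwd + d$rev)) > 1e-9))
    return("total channel must equal fwd + rev at every position")
  si <- object@seqinfo
  bad <- !(d$chrom %in% GenomeInfoDb::seqnames(si))
  if (any(bad))
    return(paste("unknown chromosome(s):",
                 paste(unique(d$chrom[bad]), collapse = ", ")))
  len <- GenomeInfoDb::seqlengths(si)[d$chrom]
  if (any(d$pos < 1L) || any(d$pos > len))
    return("positions outside chromosome bounds")
  TRUE
})

#' Anchor-relative averaged occupancy profile
#'
#' Mean collapsed tag count at each gene-oriented offset around a common
#' anchor (TSS or TTS), averaged over a gene set. Negative offsets are
#' upstream in gene orientation; offset 0 is the anchor base itself.
#'
#' @slot anchor `"TSS"` or `"TTS"`.
#' @slot offsets strictly increasing integer offsets (bp).
#' @slot values mean tag count per offset, same length as `offsets`.
#' @slot nRegions number of genes actually averaged (after bounds exclusion).
#' @slot perGeneMatrix optional genes x offsets matrix underlying the means.
#' @export
setClass("OccupancyProfile",
         slots = c(anchor = "character", offsets = "integer",
                   values = "numeric", nRegions = "integer",
                   perGeneMatrix = "matrixOrNULL"))

setValidity("OccupancyProfile", function(object) {
  if (length(object@offsets) != length(object@values))
    return("offsets and values lengths differ")
  if (is.unsorted(object@offsets, strictly = TRUE))
    return("offsets must be strictly increasing")
  if (object@nRegions < 1L) return("nRegions must be >= 1")
  if (any(object@values < 0)) return("values must be >= 0")
  m <- object@perGeneMatrix
  if (!is.null(m)) {
    if (ncol(m) != length(object@offsets))
      return("perGeneMatrix column count must match offsets")
    if (max(abs(colMeans(m) - object@values)) > 1e-9)
      return("perGeneMatrix column means must equal values")
  }
  TRUE
})

#' Per-gene binned signal matrix for heatmap display
#'
#' One row per gene: fixed-size flank bins upstream, a gene body rescaled
#' into a fixed number of bins by mean pooling, and fixed-size flank bins
#' downstream, all in gene orientation.
#'
#' @slot values genes x bins matrix of mean tag counts.
#' @slot flank flank width in bp on each side.
#' @slot bodyBins number of rescaled body bins.
#' @slot binSize flank bin width in bp.
#' @export
setClass("HeatmapMatrix",
         slots = c(values = "matrix", flank = "integer",
                   bodyBins = "integer", binSize = "integer"))

setValidity("HeatmapMatrix", function(object) {
  expected <- 2L * (object@flank %/% object@binSize) + object@bodyBins
  if (ncol(object@values) != expected)
    return("column count inconsistent with flank/binSize/bodyBins")
  if (any(object@values < 0)) return("values must be >= 0")
  TRUE
})

#' Distance-binned point counts around a feature set
#'
#' For each feature (replication origin or TAD boundary midpoint) and each
#' signed-distance bin tiling `[-maxDist, +maxDist)`, the summed weight of
#' the points (TSSs with weight 1, or tag counts) falling in that bin.
#' The enrichment curve is the per-bin mean across features, optionally
#' divided by a recorded normalizer (e.g. the total TSS count) so curves
#' from gene sets of different sizes are on a comparable scale.
#'
#' @slot featureName label of the feature set (e.g. "origins").
#' @slot binSize bin width in bp.
#' @slot maxDist half-range in bp; bins tile `[-maxDist, +maxDist)`.
#' @slot binEdges numeric vector of bin boundaries, length nBins + 1.
#' @slot counts features x bins matrix of aggregated weights.
#' @slot normalizer divisor applied to the curve; `NA` when unset.
#' @export
setClass("BinnedEnrichment",
         slots = c(featureName = "character", binSize = "integer",
                   maxDist = "integer", binEdges = "numeric",
                   counts = "matrix", normalizer = "numeric"))

setValidity("BinnedEnrichment", function(object) {
  if (object@maxDist %% object@binSize != 0L)
    return("maxDist must be a multiple of binSize")
  nb <- 2L * (object@maxDist %/% object@binSize)
  if (length(object@binEdges) != nb + 1L)
    return("binEdges length inconsistent with binSize/maxDist")
  if (max(abs(object@binEdges -
              seq(-object@maxDist, object@maxDist, by = object@binSize))) > 0)
    return("binEdges must tile [-maxDist, +maxDist) in binSize steps")
  if (ncol(object@counts) != nb)
    return("counts column count must equal number of bins")
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (!is.na(object@normalizer) && object@normalizer <= 0)
    return("normalizer must be > 0")
  TRUE
})

#' Result of the proximal-versus-distal enrichment t-test
#'
#' Per feature, the mean of the feature-proximal bins and the mean of the
#' feature-distant bins, and the two-tailed unpaired Student's t-test
#' (pooled variance by default) comparing the two vectors.
#'
#' @slot proximalHalfwidth bp half-width defining the proximal bins.
#' @slot distalOffset bp position whose containing bin pair is distal.
#' @slot proximalVector per-feature mean of the proximal bins.
#' @slot distalVector per-feature mean of the distal bins.
#' @slot statistic t statistic.
#' @slot df degrees of freedom.
#' @slot pValue two-tailed p-value.
#' @export
setClass("ProximityTestResult",
         slots = c(proximalHalfwidth = "numeric", distalOffset = "numeric",
                   proximalVector = "numeric", distalVector = "numeric",
                   statistic = "numeric", df = "numeric", pValue = "numeric"))

setValidity("ProximityTestResult", function(object) {
  if (length(object@proximalVector) != length(object@distalVector))
    return("proximal and distal vectors must have equal length")
  if (object@pValue < 0 || object@pValue > 1)
    return("pValue must be in [0, 1]")
  TRUE
})

#' qPCR cycle-threshold table
#'
#' Long-format Ct measurements from a ChIP experiment: for every
#' (sample kind, condition, replicate) there are amplicon-level Ct values,
#' and a `TelVIR` row (the subtelomeric chromosome VI right-arm control
#' region) must be present so each sample can be background-normalized.
#'
#' @slot data data.frame with columns `sample_kind` (IP/mock/input),
#'   `condition`, `amplicon`, `replicate`, `ct`.
#' @export
setClass("CtTable", slots = c(data = "data.frame"))

setValidity("CtTable", function(object) {
  d <- object@data
  need <- c("sample_kind", "condition", "amplicon", "replicate", "ct")
  if (!all(need %in% names(d)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (!all(d$sample_kind %in% c("IP", "mock", "input")))
    return("sample_kind must be one of IP, mock, input")
  if (any(!is.finite(d$ct)) || any(d$ct <= 0))
    return("ct values must be finite and > 0")
  grp <- unique(d[c("sample_kind", "condition", "replicate")])
  for (i in seq_len(nrow(grp))) {
    sel <- d$sample_kind == grp$sample_kind[i] &
      d$condition == grp$condition[i] & d$replicate == grp$replicate[i]
    if (!any(d$amplicon[sel] == "TelVIR"))
      return(sprintf("missing TelVIR control row for (%s, %s, replicate %s)",
                     grp$sample_kind[i], grp$condition[i], grp$replicate[i]))
  }
  TRUE
})

#' Raw abundance count matrix
#'
#' Non-negative integer read counts, rows are tRNA identifiers and columns
#' are samples/conditions, as produced by hybridization-based tRNA
#' abundance sequencing.
#'
#' @slot counts named numeric matrix of non-negative counts.
#' @export
setClass("CountTable", slots = c(counts = "matrix"))

setValidity("CountTable", function(object) {
  m <- object@counts
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must have row and column names")
  if (any(m < 0)) return("counts must be non-negative")
  if (any(m != round(m))) return("counts must be integers")
  TRUE
})

#' Library-size normalized abundances
#'
#' Per-million scaled counts, their log2 transform with a pseudocount, and
#' optional per-row fold changes between two named samples.
#'
#' @slot normalized matrix of normalized values.
#' @slot log2Values `log2(normalized + pseudocount)` elementwise.
#' @slot pseudocount pseudocount used in the log transform.
#' @slot method normalization method label.
#' @slot foldChanges data.frame (`id`, `fold_change`) or 0-row when no
#'   contrast was requested.
#' @export
setClass("NormalizedAbundance",
         slots = c(normalized = "matrix", log2Values = "matrix",
                   pseudocount = "numeric", method = "character",
                   foldChanges = "data.frame"))

setValidity("NormalizedAbundance", function(object) {
  if (!identical(dim(object@normalized), dim(object@log2Values)))
    return("normalized and log2Values dimensions differ")
  if (max(abs(object@log2Values -
              log2(object@normalized + object@pseudocount))) > 1e-9)
    return("log2Values must equal log2(normalized + pseudocount)")
  TRUE
})

#' Configuration for the synthetic-data generator
#'
#' All planted truths and nuisance parameters for the simulated study:
#' genome geometry, gene and feature counts, the co-localization plant,
#' tag-track peak geometry, qPCR noise, and abundance-count parameters.
#' Every generator is a pure function of this object (the seed drives a
#' per-component seed sequence so components can be regenerated
#' independently). Build with [simulationConfig()].
#'
#' @slot seed integer master seed.
#' @slot nChroms,chromLength genome geometry (bp).
#' @slot nTrna,nOrf,nOrigins,nTadBoundaries counts of placed elements.
#' @slot colocalizationFraction fraction of tRNAs planted within
#'   `colocalizationDist` of a feature (a floor; the remaining tRNAs are
#'   placed uniformly).
#' @slot colocalizationDist bp window for the plant.
#' @slot colocalizeTo `"tad_boundaries"`, `"origins"`, or `"both"`.
#' @slot peakOffset planted peak center relative to the TSS (bp,
#'   gene-oriented; default -10).
#' @slot peakSigma peak standard deviation (bp).
#' @slot peakAmplitudeMean mean tags per tRNA peak.
#' @slot backgroundRate Poisson background (tags/bp).
#' @slot ctNoiseSd qPCR measurement noise (cycles).
#' @slot ctReplicates replicates per condition in simulated Ct tables.
#' @slot trueFold named vector of planted fold enrichments per gene.
#' @slot librarySizes named vector of total counts per simulated sample.
#' @slot trueAbundances named vector of relative abundances; empty means
#'   "draw once from a Gamma(2, 1) profile under the seed".
#' @slot nAbundanceGenes number of tRNA rows when abundances are drawn.
#' @export
setClass("SimulationConfig",
         slots = c(seed = "integer", nChroms = "integer",
                   chromLength = "integer", nTrna = "integer",
                   nOrf = "integer", nOrigins = "integer",
                   nTadBoundaries = "integer",
                   colocalizationFraction = "numeric",
                   colocalizationDist = "integer", colocalizeTo = "character",
                   peakOffset = "integer", peakSigma = "numeric",
                   peakAmplitudeMean = "numeric", backgroundRate = "numeric",
                   ctNoiseSd = "numeric", ctReplicates = "integer",
                   trueFold = "numeric", librarySizes = "numeric",
                   trueAbundances = "numeric", nAbundanceGenes = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nChroms < 1L || object@chromLength < 1L)
    return("genome must have >= 1 chromosome of positive length")
  if (object@colocalizationFraction < 0 || object@colocalizationFraction > 1)
    return("colocalizationFraction must be in [0, 1]")
  if (object@colocalizationDist < 1L)
    return("colocalizationDist must be >= 1")
  if (!object@colocalizeTo %in% c("tad_boundaries", "origins", "both"))
    return("colocalizeTo must be tad_boundaries, origins or both")
  if (object@peakSigma < 0 || object@peakAmplitudeMean < 0 ||
      object@backgroundRate < 0 || object@ctNoiseSd < 0)
    return("sigma, amplitude, background rate and ct noise must be >= 0")
  if (any(object@trueFold <= 0)) return("trueFold values must be > 0")
  if (any(object@librarySizes <= 0)) return("librarySizes must be > 0")
  if (length(object@trueAbundances) && any(object@trueAbundances <= 0))
    return("trueAbundances must be > 0")
  TRUE
})
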