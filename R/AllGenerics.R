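#' @importFrom GenomeInfoDb seqinfo seqnames seqlengths
NULL

#' Total tag count of a track
#' @param x a [TagTrack-class].
#' @return numeric scalar, the sum of the collapsed channel.
#' @export
setGeneric("totalTags", function(x) standardGeneric("totalTags"))

#' Collapsed (forward + reverse) per-position counts
#' @param x a [TagTrack-class].
#' @return data.frame with columns `chrom`, `pos`, `count`.
#' @export
setGeneric("collapsedCounts", function(x) standardGeneric("collapsedCounts"))

#' Profile offsets and values
#' @param x an [OccupancyProfile-class].
#' @return integer offsets / numeric mean values.
#' @export
setGeneric("profileOffsets", function(x) standardGeneric("profileOffsets"))

#' @rdname profileOffsets
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' Per-bin enrichment curve (mean across features, normalized if set)
#' @param x a [BinnedEnrichment-class].
#' @return numeric vector, one value per bin.
#' @export
setGeneric("binCurve", function(x) standardGeneric("binCurve"))

#' Per-feature bin count matrix
#' @param x a [BinnedEnrichment-class].
#' @return features x bins numeric matrix.
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

setMethod("totalTags", "TagTrack", function(x) sum(x@data$total))

setMethod("collapsedCounts", "TagTrack", function(x) {
  data.frame(chrom = x@data$chrom, pos = x@data$pos, count = x@data$total)
})

setMethod("seqinfo", "TagTrack", function(x) x@seqinfo)

setMethod("profileOffsets", "OccupancyProfile", function(x) x@offsets)
setMethod("profileValues", "OccupancyProfile", function(x) x@values)

setMethod("binCounts", "BinnedEnrichment", function(x) x@counts)

setMethod("binCurve", "BinnedEnrichment", function(x) {
  curve <- colMeans(x@counts)
  if (!is.na(x@normalizer)) curve <- curve / x@normalizer
  curve
})

setMethod("show", "TagTrack", function(object) {
  cat(sprintf("TagTrack: %d occupied positions on %d chromosome(s), %g tags total\n",
              nrow(object@data),
              length(unique(object@data$chrom)), totalTags(object)))
})

setMethod("show", "OccupancyProfile", function(object) {
  cat(sprintf("OccupancyProfile (%s-anchored): offsets %d..%d, %d genes averaged\n",
              object@anchor, min(object@offsets), max(object@offsets),
              object@nRegions))
})

setMethod("show", "BinnedEnrichment", function(object) {
  cat(sprintf("BinnedEnrichment around '%s': %d features, %d bins of %d bp over [-%d, %d)%s\n",
              object@featureName, nrow(object@counts), ncol(object@counts),
              object@binSize, object@maxDist, object@maxDist,
              if (is.na(object@normalizer)) ""
              else sprintf(", normalized by %g", object@normalizer)))
})

setMethod("show", "ProximityTestResult", function(object) {
  cat(sprintf("Proximal (+/-%g bp) vs distal (+/-%g bp) t-test: t = %.4g, df = %.4g, p = %.4g\n",
              object@proximalHalfwidth, object@distalOffset,
              object@statistic, object@df, object@pValue))
})

setMethod("show", "CtTable", function(object) {
  d <- object@data
  cat(sprintf("CtTable: %d measurements, %d amplicon(s), %d condition(s)\n",
              nrow(d), length(unique(d$amplicon)),
              length(unique(d$condition))))
})

setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable: %d features x %d samples\n",
              nrow(object@counts), ncol(object@counts)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: seed %d; %d chrom x %d bp; %d tRNA, ",
                     "%d ORF, %d origins, %d TAD boundaries; coloc %.2f within %d bp of %s\n"),
              object@seed, object@nChroms, object@chromLength, object@nTrna,
              object@nOrf, object@nOrigins, object@nTadBoundaries,
              object@colocalizationFraction, object@colocalizationDist,
              object@colocalizeTo))
})
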