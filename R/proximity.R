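# Distance-binned feature-proximity enrichment and the
# proximal-versus-distal two-tailed t-test.

#' Weighted point sets for proximity binning
#'
#' `tssPoints()` turns a gene set into unit-weight TSS points;
#' `trackPoints()` turns a tag track into points weighted by the
#' collapsed per-position counts.
#'
#' @param genes GRanges from [geneRanges()].
#' @return data.frame with columns `chrom`, `pos`, `weight`.
#' @export
tssPoints <- function(genes) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(genes)),
             pos = tssSites(genes), weight = 1)
}

#' @rdname tssPoints
#' @param track a [TagTrack-class].
#' @export
trackPoints <- function(track) {
  d <- collapsedCounts(track)
  data.frame(chrom = d$chrom, pos = d$pos, weight = d$count)
}

#' Distance-binned point counts around features
#'
#' For each feature point and each point on the same chromosome whose
#' signed distance `pos(point) - pos(feature)` falls in
#' `[-maxDist, +maxDist)`, the point's weight is added to the half-open
#' bin containing that distance. A point near two features contributes to
#' both rows (aggregation, not nearest-feature assignment), so total
#' matrix mass is conserved when features are well separated.
#'
#' @param points data.frame with `chrom`, `pos` and optionally `weight`
#'   (default 1) -- see [tssPoints()] / [trackPoints()].
#' @param features GRanges of width-1 feature points; non-empty.
#' @param binSize bin width in bp (`> 0`).
#' @param maxDist half-range in bp (a multiple of `binSize`).
#' @param featureName label stored on the result.
#' @return a [BinnedEnrichment-class].
#' @export
relativeBinCounts <- function(points, features, binSize, maxDist,
                              featureName = "features") {
  binSize <- as.integer(binSize); maxDist <- as.integer(maxDist)
  if (binSize <= 0L) stop("binSize must be > 0")
  if (maxDist %% binSize != 0L) stop("maxDist must be a multiple of binSize")
  if (length(features) == 0L) stop("features must be non-empty")
  if (is.null(points$weight)) points$weight <- rep(1, nrow(points))
  nBins <- 2L * (maxDist %/% binSize)
  edges <- seq(-maxDist, maxDist, by = binSize)
  counts <- matrix(0, nrow = length(features), ncol = nBins)
  fchr <- as.character(GenomeInfoDb::seqnames(features))
  fpos <- start(features)
  byChrom <- split(points[c("pos", "weight")], points$chrom)
  for (f in seq_along(features)) {
    p <- byChrom[[fchr[f]]]
    if (is.null(p) || nrow(p) == 0L) next
    d <- p$pos - fpos[f]
    sel <- d >= -maxDist & d < maxDist
    if (!any(sel)) next
    idx <- (d[sel] + maxDist) %/% binSize + 1L
    acc <- rowsum(p$weight[sel], idx)
    counts[f, as.integer(rownames(acc))] <-
      counts[f, as.integer(rownames(acc))] + acc[, 1]
  }
  rn <- S4Vectors::mcols(features)$gene_id
  rownames(counts) <- if (!is.null(rn)) rn else
    sprintf("%s_%04d", featureName, seq_along(features))
  colnames(counts) <- sprintf("[%d,%d)", utils::head(edges, -1L),
                              utils::tail(edges, -1L))
  new("BinnedEnrichment", featureName = featureName, binSize = binSize,
      maxDist = maxDist, binEdges = edges, counts = counts,
      normalizer = NA_real_)
}

#' Scale an enrichment curve by a total point count
#'
#' Records `totalCount` as the curve normalizer (the per-feature count
#' matrix is unchanged), bringing curves from gene sets of different
#' sizes -- e.g. tRNAs versus the ORF control -- onto a comparable scale.
#'
#' @param binned a [BinnedEnrichment-class].
#' @param totalCount positive divisor (e.g. number of TSSs aggregated).
#' @return a [BinnedEnrichment-class] with the normalizer set.
#' @export
normalizeCurve <- function(binned, totalCount) {
  if (!is.numeric(totalCount) || length(totalCount) != 1L ||
      !is.finite(totalCount) || totalCount <= 0)
    stop("totalCount must be a positive number")
  initialize(binned, normalizer = as.numeric(totalCount))
}

# Shared two-tailed unpaired t-test core (pooled variance by default),
# with the degenerate cases defined before dispatching to stats::t.test:
# zero variance with equal means is "no difference" (t = 0, p = 1);
# zero variance with unequal means has no defined t and is an error.
.tTestCore <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 values per group")
  scale <- max(abs(c(a, b)), 1)
  eps <- 1e-12 * scale
  if (stats::sd(a) < eps && stats::sd(b) < eps) {
    if (abs(mean(a) - mean(b)) < eps)
      return(list(statistic = 0, df = length(a) + length(b) - 2,
                  pValue = 1))
    stop("degenerate test: zero variance with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       pValue = unname(ht$p.value))
}

#' Proximal-versus-distal enrichment test
#'
#' For each feature, the mean of the bins overlapping
#' `[-proximalHalfwidth, +proximalHalfwidth)` (proximal) and the mean of
#' the bin pair containing `-distalOffset` and `+distalOffset` (distal),
#' compared by a two-tailed unpaired Student's t-test with pooled
#' variance. This is the significance machinery behind statements like
#' "tRNA genes are enriched around replication origins": under no
#' co-localization the proximal and distal bin means share a
#' distribution, and planted proximity inflates only the proximal side.
#'
#' @param binned a [BinnedEnrichment-class] with `>= 2` features.
#' @param proximalHalfwidth bp; e.g. 500 for TAD boundaries, 1500 for
#'   replication origins.
#' @param distalOffset bp; e.g. 2500 for TAD boundaries, 5000 for
#'   origins.
#' @param distalMode `"pair"` (default: the single bin pair containing
#'   the offsets) or `"beyond"` (every bin entirely outside
#'   `[-distalOffset, +distalOffset]`).
#' @param vectors `"per_feature"` (default: one proximal and one distal
#'   mean per feature, n = feature count) or `"bin_means"` (the curve
#'   values of the proximal and distal bins).
#' @param welch use Welch's unequal-variance test instead of pooled.
#' @return a [ProximityTestResult-class].
#' @export
proximalDistalTest <- function(binned, proximalHalfwidth, distalOffset,
                               distalMode = c("pair", "beyond"),
                               vectors = c("per_feature", "bin_means"),
                               welch = FALSE) {
  distalMode <- match.arg(distalMode)
  vectors <- match.arg(vectors)
  edges <- binned@binEdges
  lo <- utils::head(edges, -1L); hi <- utils::tail(edges, -1L)
  prox <- which(lo < proximalHalfwidth & hi > -proximalHalfwidth)
  dist <- if (distalMode == "pair") {
    which((lo <= -distalOffset & -distalOffset < hi) |
            (lo <= distalOffset & distalOffset < hi))
  } else {
    which(hi <= -distalOffset | lo >= distalOffset)
  }
  if (!length(prox) || !length(dist))
    stop("proximal/distal windows select no bins; widen maxDist")
  if (length(intersect(prox, dist)))
    stop("proximal and distal bin sets overlap; adjust windows")
  cm <- binned@counts
  if (vectors == "per_feature") {
    if (nrow(cm) < 2L) stop("need at least 2 features")
    a <- rowMeans(cm[, prox, drop = FALSE])
    b <- rowMeans(cm[, dist, drop = FALSE])
  } else {
    curve <- binCurve(binned)
    a <- curve[prox]; b <- curve[dist]
  }
  res <- .tTestCore(a, b, welch = welch)
  new("ProximityTestResult",
      proximalHalfwidth = as.numeric(proximalHalfwidth),
      distalOffset = as.numeric(distalOffset),
      proximalVector = unname(a), distalVector = unname(b),
      statistic = res$statistic, df = res$df, pValue = res$pValue)
}

#' Default proximity-analysis configuration
#'
#' Bin sizes and proximal/distal windows per feature type: 1000-bp bins
#' for TSS signals and 100-bp bins for tag signals; for TAD boundaries
#' proximal is +/-0.5 kb and distal +/-2.5 kb (narrow enrichment range),
#' for replication origins proximal +/-1.5 kb and distal +/-5 kb
#' (broader range). `maxDist` is the smallest multiple of the TSS bin
#' size covering the distal offset.
#'
#' @param tssBinSize,tagBinSize bin widths in bp.
#' @param featureWindows named list: per feature-set name, a list with
#'   `proximal`, `distal`, `maxDist` (bp).
#' @return a list used by [runProximityAnalysis()].
#' @export
proximityConfig <- function(tssBinSize = 1000L, tagBinSize = 100L,
                            featureWindows = list(
                              tad_boundaries = list(proximal = 500L,
                                                    distal = 2500L,
                                                    maxDist = 3000L),
                              origins = list(proximal = 1500L,
                                             distal = 5000L,
                                             maxDist = 6000L))) {
  list(tssBinSize = as.integer(tssBinSize),
       tagBinSize = as.integer(tagBinSize),
       featureWindows = featureWindows)
}

#' End-to-end feature-proximity analysis
#'
#' For each feature set: the normalized tRNA-TSS enrichment curve, the
#' ORF-TSS control curve (each normalized by its total TSS count), the
#' optional tag-track curve (normalized to tags per million), and the
#' proximal-versus-distal test per signal. Deterministic given its
#' inputs.
#'
#' @param genes GRanges with `gene_class` (`tRNA` rows are the signal,
#'   `ORF` rows the control; either may be absent).
#' @param features named list of width-1 feature GRanges (names must
#'   appear in `config$featureWindows`).
#' @param track optional [TagTrack-class].
#' @param config from [proximityConfig()].
#' @return list with one element per feature set, each holding `curves`
#'   (data.frame: bin bounds, center, one normalized column per signal)
#'   and `tests` (data.frame: signal, t, df, p, n_features), plus the
#'   `config` used.
#' @export
runProximityAnalysis <- function(genes, features, track = NULL,
                                 config = proximityConfig()) {
  if (!is.list(features) || is.null(names(features)))
    stop("features must be a named list of feature-point GRanges")
  missing <- setdiff(names(features), names(config$featureWindows))
  if (length(missing))
    stop("no featureWindows config for: ", paste(missing, collapse = ", "))
  cls <- S4Vectors::mcols(genes)$gene_class
  trna <- genes[cls == "tRNA"]
  orf <- genes[cls == "ORF"]
  out <- list()
  for (fs in names(features)) {
    w <- config$featureWindows[[fs]]
    signals <- list()
    if (length(trna))
      signals$trna <- normalizeCurve(
        relativeBinCounts(tssPoints(trna), features[[fs]],
                          config$tssBinSize, w$maxDist, featureName = fs),
        length(trna))
    if (length(orf))
      signals$orf <- normalizeCurve(
        relativeBinCounts(tssPoints(orf), features[[fs]],
                          config$tssBinSize, w$maxDist, featureName = fs),
        length(orf))
    if (!is.null(track))
      signals$tags <- normalizeCurve(
        relativeBinCounts(trackPoints(track), features[[fs]],
                          config$tagBinSize, w$maxDist, featureName = fs),
        totalTags(track) / 1e6)
    if (!length(signals)) stop("no signals to analyze for ", fs)
    tests <- do.call(rbind, lapply(names(signals), function(sig) {
      tr <- proximalDistalTest(signals[[sig]], w$proximal, w$distal)
      data.frame(signal = sig, t = tr@statistic, df = tr@df,
                 p = tr@pValue, n_features = length(tr@proximalVector))
    }))
    # signals may use different bin sizes; report each on its own grid
    curveTabs <- lapply(names(signals), function(sig) {
      e <- signals[[sig]]@binEdges
      data.frame(signal = sig,
                 bin_lo = utils::head(e, -1L), bin_hi = utils::tail(e, -1L),
                 bin_center = (utils::head(e, -1L) + utils::tail(e, -1L)) / 2,
                 value = binCurve(signals[[sig]]))
    })
    out[[fs]] <- list(curves = do.call(rbind, curveTabs), tests = tests,
                      binned = signals)
  }
  out$config <- config
  out
}
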