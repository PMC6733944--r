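# Anchor-relative occupancy profiling, the pol II gene-end confound
# filter, ORF density, heatmap matrices and windowed means.

# Vectorized sparse lookup of collapsed counts; absent positions read 0.
.lookupTotals <- function(track, chrom, pos) {
  q <- data.table(chrom = chrom, pos = as.integer(pos))
  td <- as.data.table(track@data)[, c("chrom", "pos", "total")]
  res <- td[q, on = c("chrom", "pos")]
  out <- res$total
  out[is.na(out)] <- 0
  out
}

.strandSign <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", 1L, -1L)
}

#' Metagene occupancy profile around a common anchor
#'
#' For every gene-oriented offset in `[-flank, +flank]` (0 = the anchor
#' base), the mean collapsed tag count over the gene set at the genomic
#' position mapping to that offset. Minus-strand genes are read right to
#' left, so "upstream" always means upstream in gene orientation. Genes
#' whose window would run past a chromosome end are excluded (with a
#' message) so every averaged row has equal length.
#'
#' @param track a [TagTrack-class].
#' @param genes GRanges from [geneRanges()]; non-empty.
#' @param flank window half-width in bp (`>= 1`).
#' @param anchor `"TSS"` (default) or `"TTS"`.
#' @param keepMatrix retain the per-gene matrix underlying the means.
#' @param perMillion scale values by `1e6 / totalTags(track)`.
#' @return an [OccupancyProfile-class].
#' @export
computeProfile <- function(track, genes, flank = 300L,
                           anchor = c("TSS", "TTS"), keepMatrix = FALSE,
                           perMillion = FALSE) {
  anchor <- match.arg(anchor)
  flank <- as.integer(flank)
  if (length(genes) == 0L) stop("genes must be non-empty")
  if (flank < 1L) stop("flank must be >= 1")
  a <- if (anchor == "TSS") tssSites(genes) else ttsSites(genes)
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  len <- GenomeInfoDb::seqlengths(track@seqinfo)[chrom]
  ok <- (a - flank) >= 1L & (a + flank) <= len
  if (any(!ok))
    message(sum(!ok), " gene(s) excluded: window exceeds chromosome bounds")
  if (!any(ok)) stop("all genes excluded: windows exceed chromosome bounds")
  genes <- genes[ok]; a <- a[ok]; chrom <- chrom[ok]
  s <- .strandSign(genes)
  offsets <- seq.int(-flank, flank)
  nOff <- length(offsets)
  pos <- rep(a, each = nOff) + rep(s, each = nOff) * offsets
  vals <- .lookupTotals(track, rep(chrom, each = nOff), pos)
  m <- matrix(vals, nrow = length(genes), ncol = nOff, byrow = TRUE)
  if (perMillion) {
    tt <- totalTags(track)
    if (tt <= 0) stop("cannot per-million normalize an empty track")
    m <- m * 1e6 / tt
  }
  rownames(m) <- mcols(genes)$gene_id
  new("OccupancyProfile", anchor = anchor, offsets = as.integer(offsets),
      values = unname(colMeans(m)), nRegions = length(genes),
      perGeneMatrix = if (keepMatrix) m else NULL)
}

#' Filter tRNA genes flanked by pol II gene ends
#'
#' Removes tRNA genes whose occupancy window is confounded by nearby pol
#' II-transcribed gene ends. A gene end is either coordinate (start or
#' end) of a pol II gene; an end is "within" `window` bp of a side when
#' its distance from the corresponding tRNA body edge is `<= window` (an
#' end inside the tRNA body counts on both sides). In `"both_sides"` mode
#' a tRNA is removed only when flanked on both its upstream and
#' downstream sides; `"either_side"` removes on one-sided proximity, so
#' it always retains a subset of the `both_sides` result.
#'
#' @param trnas tRNA GRanges.
#' @param pol2Genes pol II (e.g. ORF) GRanges.
#' @param window distance threshold in bp (`> 0`; 0 removes only
#'   touching ends).
#' @param mode `"both_sides"` (default) or `"either_side"`.
#' @return the retained tRNA subset.
#' @export
filterFlankedGenes <- function(trnas, pol2Genes, window = 300L,
                               mode = c("both_sides", "either_side")) {
  mode <- match.arg(mode)
  if (window < 0) stop("window must be >= 0")
  if (length(trnas) == 0L || length(pol2Genes) == 0L) return(trnas)
  echr <- rep(as.character(GenomeInfoDb::seqnames(pol2Genes)), 2L)
  epos <- c(start(pol2Genes), end(pol2Genes))
  tchr <- as.character(GenomeInfoDb::seqnames(trnas))
  ts <- start(trnas); te <- end(trnas)
  removed <- vapply(seq_along(trnas), function(i) {
    e <- epos[echr == tchr[i]]
    if (!length(e)) return(FALSE)
    inside <- e > ts[i] & e < te[i]
    left <- (e <= ts[i] & ts[i] - e <= window) | inside
    right <- (e >= te[i] & e - te[i] <= window) | inside
    if (mode == "both_sides") any(left) && any(right)
    else any(left) || any(right)
  }, logical(1))
  trnas[!removed]
}

#' ORF density in fixed windows around tRNA gene bodies
#'
#' Counts, in every `step`-bp window up to `span` bp upstream and
#' downstream of the tRNA gene body (gene-oriented), the ORFs whose
#' proximal end falls in that window, summed over all tRNAs. The proximal
#' end of an ORF is the body-edge coordinate nearer the tRNA; ORFs
#' overlapping the tRNA body are not assigned to any window. With
#' `sameStrand = TRUE` (the default) only ORFs on the tRNA's strand are
#' counted.
#'
#' @param trnas,orfs GRanges from [geneRanges()].
#' @param step window width in bp.
#' @param span total distance covered on each side (a multiple of `step`).
#' @param sameStrand restrict to strand-matched ORFs.
#' @return data.frame with columns `side` (upstream/downstream),
#'   `dist_lo`, `dist_hi` (half-open window in bp from the body edge) and
#'   `count`.
#' @export
orfDensity <- function(trnas, orfs, step = 100L, span = 1000L,
                       sameStrand = TRUE) {
  step <- as.integer(step); span <- as.integer(span)
  if (span %% step != 0L) stop("span must be a multiple of step")
  nW <- span %/% step
  up <- integer(nW); down <- integer(nW)
  ochr <- as.character(GenomeInfoDb::seqnames(orfs))
  ost <- as.character(strand(orfs))
  tchr <- as.character(GenomeInfoDb::seqnames(trnas))
  tst <- as.character(strand(trnas))
  for (i in seq_along(trnas)) {
    sel <- ochr == tchr[i]
    if (sameStrand) sel <- sel & ost == tst[i]
    if (!any(sel)) next
    os <- start(orfs)[sel]; oe <- end(orfs)[sel]
    ts <- start(trnas)[i]; te <- end(trnas)[i]
    dRight <- (os - te)[os > te]   # ORFs fully to the genomic right
    dLeft <- (ts - oe)[oe < ts]    # ORFs fully to the genomic left
    if (tst[i] == "+") { dDown <- dRight; dUp <- dLeft }
    else               { dDown <- dLeft;  dUp <- dRight }
    kD <- dDown %/% step; kU <- dUp %/% step
    kD <- kD[kD < nW]; kU <- kU[kU < nW]
    down <- down + tabulate(kD + 1L, nW)
    up <- up + tabulate(kU + 1L, nW)
  }
  data.frame(side = rep(c("upstream", "downstream"), each = nW),
             dist_lo = rep(seq.int(0L, span - step, step), 2L),
             dist_hi = rep(seq.int(step, span, step), 2L),
             count = c(up, down))
}

#' Per-gene binned signal matrix (heatmap rows)
#'
#' One row per gene: `flank/binSize` mean-pooled bins upstream of the
#' gene body, the body rescaled into `bodyBins` bins by mean pooling
#' (linear interpolation when the gene is shorter than `bodyBins`, with a
#' message), and the downstream flank -- all gene-oriented. Genes whose
#' flank runs past a chromosome end are excluded (message). Rows are
#' ordered by descending row sum by default; ordering is presentation
#' only.
#'
#' @param track a [TagTrack-class].
#' @param genes GRanges; non-empty.
#' @param flank flank width in bp (a multiple of `binSize`).
#' @param bodyBins number of rescaled body bins.
#' @param binSize flank bin width in bp.
#' @param sortRows order rows by descending row sum.
#' @return a [HeatmapMatrix-class].
#' @export
heatmapMatrix <- function(track, genes, flank = 1000L, bodyBins = 50L,
                          binSize = 10L, sortRows = TRUE) {
  flank <- as.integer(flank); bodyBins <- as.integer(bodyBins)
  binSize <- as.integer(binSize)
  if (length(genes) == 0L) stop("genes must be non-empty")
  if (flank %% binSize != 0L) stop("flank must be a multiple of binSize")
  nF <- flank %/% binSize
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  len <- GenomeInfoDb::seqlengths(track@seqinfo)[chrom]
  ok <- (start(genes) - flank) >= 1L & (end(genes) + flank) <= len
  if (any(!ok))
    message(sum(!ok), " gene(s) excluded: flank exceeds chromosome bounds")
  if (!any(ok)) stop("all genes excluded: flanks exceed chromosome bounds")
  genes <- genes[ok]; chrom <- chrom[ok]
  shortSeen <- FALSE
  pool <- function(v, nb) {
    if (length(v) >= nb) {
      idx <- floor(seq(0, length(v), length.out = nb + 1L))
      vapply(seq_len(nb), function(b)
        mean(v[(idx[b] + 1L):idx[b + 1L]]), numeric(1))
    } else {
      shortSeen <<- TRUE
      stats::approx(seq_along(v), v, n = nb)$y
    }
  }
  rows <- t(vapply(seq_along(genes), function(i) {
    s <- .strandSign(genes)[i]
    gs <- start(genes)[i]; ge <- end(genes)[i]
    if (s == 1L) {
      posUp <- seq.int(gs - flank, gs - 1L)
      posBody <- seq.int(gs, ge)
      posDown <- seq.int(ge + 1L, ge + flank)
    } else {
      posUp <- seq.int(ge + flank, ge + 1L)
      posBody <- seq.int(ge, gs)
      posDown <- seq.int(gs - 1L, gs - flank)
    }
    allPos <- c(posUp, posBody, posDown)
    v <- .lookupTotals(track, rep(chrom[i], length(allPos)), allPos)
    nUp <- length(posUp); nBody <- length(posBody)
    c(colMeans(matrix(v[seq_len(nUp)], nrow = binSize)),
      pool(v[nUp + seq_len(nBody)], bodyBins),
      colMeans(matrix(v[nUp + nBody + seq_len(flank)], nrow = binSize)))
  }, numeric(2L * nF + bodyBins)))
  if (shortSeen)
    message("gene(s) shorter than bodyBins: body bins interpolated")
  rownames(rows) <- mcols(genes)$gene_id
  colnames(rows) <- c(sprintf("u%03d", seq_len(nF)),
                      sprintf("b%03d", seq_len(bodyBins)),
                      sprintf("d%03d", seq_len(nF)))
  if (sortRows) rows <- rows[order(-rowSums(rows)), , drop = FALSE]
  new("HeatmapMatrix", values = rows, flank = flank,
      bodyBins = bodyBins, binSize = binSize)
}

#' Mean occupancy over a gene-oriented window
#'
#' Mean collapsed tag count over offsets `[relStart, relEnd]` (inclusive,
#' gene-oriented, anchored at the TSS). Out-of-bounds positions are
#' truncated to the chromosome (with a message) rather than excluding the
#' gene, since a single-gene mean does not need equal-length rows.
#'
#' @param track a [TagTrack-class].
#' @param gene a single-gene GRanges.
#' @param relStart,relEnd window bounds in bp relative to the TSS
#'   (`relStart < relEnd`; negative = upstream).
#' @return numeric mean count.
#' @export
meanWindowOccupancy <- function(track, gene, relStart, relEnd) {
  if (length(gene) != 1L) stop("gene must be a single record")
  if (relStart >= relEnd) stop("need relStart < relEnd")
  a <- tssSites(gene)
  s <- .strandSign(gene)
  chrom <- as.character(GenomeInfoDb::seqnames(gene))
  pos <- a + s * seq.int(relStart, relEnd)
  len <- GenomeInfoDb::seqlengths(track@seqinfo)[[chrom]]
  inb <- pos >= 1L & pos <= len
  if (!any(inb)) stop("window lies entirely outside the chromosome")
  if (any(!inb)) message("window truncated to chromosome bounds")
  mean(.lookupTotals(track, rep(chrom, sum(inb)), pos[inb]))
}

#' Sample Pearson correlation with explicit degenerate handling
#'
#' The correlation statistic used for occupancy comparisons. Inputs must
#' be equal-length (`>= 3`), finite, and have non-zero variance; a
#' zero-variance input raises an error rather than returning a numeric.
#'
#' @param xs,ys numeric vectors.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearsonR <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(xs)) || !all(is.finite(ys)))
    stop("inputs must be finite")
  if (stats::var(xs) == 0 || stats::var(ys) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(xs, ys)
}
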