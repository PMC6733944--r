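# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops, no shared code with the package
# internals) so they stay independent of the paths they check.

si1 <- function(len = 10000L) GenomeInfoDb::Seqinfo("chrI", len)

si2 <- function(len = c(10000L, 20000L))
  GenomeInfoDb::Seqinfo(c("chrI", "chrII"), len)

mkGenes <- function(chrom, start, end, strand, class = "tRNA", si,
                    ids = NULL) {
  if (is.null(ids)) ids <- sprintf("g%03d", seq_along(chrom))
  geneRanges(ids, chrom, start, end, strand, class, si)
}

mkTrack <- function(chrom, pos, fwd, rev = rep(0, length(pos)), si) {
  tagTrack(chrom, pos, fwd, rev, si)
}

mkPoints <- function(chrom, pos, si, name = "pts") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos), seqinfo = si)
}

# position -> collapsed count, scalar, by linear scan
lookup1 <- function(track, chrom, pos) {
  d <- collapsedCounts(track)
  hit <- d$chrom == chrom & d$pos == pos
  if (any(hit)) sum(d$count[hit]) else 0
}

# naive per-gene per-offset profile
bruteProfile <- function(track, genes, flank) {
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  len <- GenomeInfoDb::seqlengths(seqinfo(track))[chrom]
  tss <- tssSites(genes)
  keep <- tss - flank >= 1 & tss + flank <= len
  genes <- genes[keep]; chrom <- chrom[keep]; tss <- tss[keep]
  offsets <- -flank:flank
  m <- matrix(0, length(genes), length(offsets))
  for (i in seq_along(genes)) {
    s <- if (as.character(GenomicRanges::strand(genes)[i]) == "+") 1 else -1
    for (j in seq_along(offsets))
      m[i, j] <- lookup1(track, chrom[i], tss[i] + s * offsets[j])
  }
  colMeans(m)
}

# naive all-pairs distance binning
bruteBinCounts <- function(points, features, binSize, maxDist) {
  if (is.null(points$weight)) points$weight <- 1
  fchr <- as.character(GenomeInfoDb::seqnames(features))
  fpos <- GenomicRanges::start(features)
  nBins <- 2 * maxDist / binSize
  m <- matrix(0, length(features), nBins)
  for (f in seq_along(features)) for (p in seq_len(nrow(points))) {
    if (points$chrom[p] != fchr[f]) next
    d <- points$pos[p] - fpos[f]
    if (d < -maxDist || d >= maxDist) next
    m[f, floor((d + maxDist) / binSize) + 1] <-
      m[f, floor((d + maxDist) / binSize) + 1] + points$weight[p]
  }
  m
}

# naive all-pairs TSS-distance filter
bruteGenesWithin <- function(features, genes, maxDist) {
  fchr <- as.character(GenomeInfoDb::seqnames(features))
  fpos <- GenomicRanges::start(features)
  keep <- logical(length(genes))
  gchr <- as.character(GenomeInfoDb::seqnames(genes))
  tss <- tssSites(genes)
  for (i in seq_along(genes)) for (f in seq_along(features)) {
    if (gchr[i] == fchr[f] && abs(tss[i] - fpos[f]) <= maxDist)
      keep[i] <- TRUE
  }
  genes[keep]
}

# naive both/either-side pol II gene-end filter
bruteFilterFlanked <- function(trnas, pol2, window, mode) {
  echr <- rep(as.character(GenomeInfoDb::seqnames(pol2)), 2)
  epos <- c(GenomicRanges::start(pol2), GenomicRanges::end(pol2))
  keep <- logical(length(trnas))
  for (i in seq_along(trnas)) {
    ts <- GenomicRanges::start(trnas)[i]
    te <- GenomicRanges::end(trnas)[i]
    tc <- as.character(GenomeInfoDb::seqnames(trnas))[i]
    left <- FALSE; right <- FALSE
    for (j in seq_along(epos)) {
      if (echr[j] != tc) next
      e <- epos[j]
      if (e > ts && e < te) { left <- TRUE; right <- TRUE }
      if (e <= ts && ts - e <= window) left <- TRUE
      if (e >= te && e - te <= window) right <- TRUE
    }
    removed <- if (mode == "both_sides") left && right else left || right
    keep[i] <- !removed
  }
  trnas[keep]
}

# reflect every coordinate (pos -> L + 1 - pos) and flip strands
reflectGenes <- function(genes) {
  si <- GenomeInfoDb::seqinfo(genes)
  len <- GenomeInfoDb::seqlengths(si)[
    as.character(GenomeInfoDb::seqnames(genes))]
  s <- as.character(GenomicRanges::strand(genes))
  geneRanges(S4Vectors::mcols(genes)$gene_id,
             as.character(GenomeInfoDb::seqnames(genes)),
             len + 1L - GenomicRanges::end(genes),
             len + 1L - GenomicRanges::start(genes),
             ifelse(s == "+", "-", "+"),
             S4Vectors::mcols(genes)$gene_class, si)
}

reflectTrack <- function(track) {
  d <- track@data
  len <- GenomeInfoDb::seqlengths(seqinfo(track))[d$chrom]
  tagTrack(d$chrom, len + 1L - d$pos, d$rev, d$fwd, seqinfo(track))
}

reflectPoints <- function(features) {
  si <- GenomeInfoDb::seqinfo(features)
  len <- GenomeInfoDb::seqlengths(si)[
    as.character(GenomeInfoDb::seqnames(features))]
  p <- len + 1L - GenomicRanges::start(features)
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(features),
                         IRanges::IRanges(p, p), seqinfo = si)
}

# two-sample permutation p-value for the absolute mean difference
permutationP <- function(a, b, B = 10000, seed = 42) {
  withr::with_seed(seed, {
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b)
    n <- length(a)
    hits <- 0
    for (i in seq_len(B)) {
      idx <- sample.int(length(pool), n)
      if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12)
        hits <- hits + 1
    }
    hits / B
  })
}
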