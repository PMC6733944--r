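# Synthetic-data generator: genomes with planted co-localization, tag
# tracks with planted TSS-proximal peaks, Ct tables with planted fold
# enrichments, and multinomial count tables with planted abundances.
# Every generator is a pure function of its SimulationConfig; the master
# seed drives a fixed per-component offset (genome +0, track +1, Ct +2,
# counts +3) so components regenerate independently.

#' Build a simulation configuration
#'
#' Defaults describe a desk-scale study emulating the budding-yeast
#' situation at roughly one tenth genome size: 4 chromosomes of 300 kb,
#' 150 tRNA genes of 70-120 bp, 300 ORFs of 500-2000 bp, 40 replication
#' origins and 40 TAD boundaries, a Poisson tag background of 0.05
#' tags/bp, and per-tRNA peaks of ~100 tags centered 10 bp upstream of
#' the TSS with a 5-bp spread (the near-base-pair sharpness ChIP-exo
#' resolves). No co-localization is planted by default.
#'
#' @param seed master seed (integer, `< 2^31 - 8`).
#' @param nChroms,chromLength,nTrna,nOrf,nOrigins,nTadBoundaries genome
#'   geometry and element counts.
#' @param colocalizationFraction,colocalizationDist,colocalizeTo the
#'   co-localization plant: `round(fraction * nTrna)` tRNAs get their TSS
#'   placed within `colocalizationDist` bp of a feature of the chosen
#'   set(s); the remaining tRNAs are placed uniformly (no exclusion
#'   zone), so the planted count is a floor, not an exact total.
#' @param peakOffset,peakSigma,peakAmplitudeMean,backgroundRate tag-track
#'   peak geometry and background.
#' @param ctNoiseSd,ctReplicates,trueFold qPCR simulation parameters.
#' @param librarySizes,trueAbundances,nAbundanceGenes count-table
#'   simulation parameters.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, nChroms = 4L,
                             chromLength = 300000L, nTrna = 150L,
                             nOrf = 300L, nOrigins = 40L,
                             nTadBoundaries = 40L,
                             colocalizationFraction = 0,
                             colocalizationDist = 500L,
                             colocalizeTo = "tad_boundaries",
                             peakOffset = -10L, peakSigma = 5,
                             peakAmplitudeMean = 100,
                             backgroundRate = 0.05, ctNoiseSd = 0.2,
                             ctReplicates = 3L,
                             trueFold = c(tQ1 = 4, tE1 = 2.5, tL1 = 1,
                                          tS1 = 8, tV1 = 1.5, tM1 = 2),
                             librarySizes = c(wt = 200000, mut = 200000),
                             trueAbundances = numeric(0),
                             nAbundanceGenes = 50L) {
  if (!is.numeric(seed) || !is.finite(seed) || seed >= 2^31 - 8)
    stop("seed must be an integer < 2^31 - 8")
  seed <- as.integer(seed)
  new("SimulationConfig", seed = seed, nChroms = as.integer(nChroms),
      chromLength = as.integer(chromLength), nTrna = as.integer(nTrna),
      nOrf = as.integer(nOrf), nOrigins = as.integer(nOrigins),
      nTadBoundaries = as.integer(nTadBoundaries),
      colocalizationFraction = colocalizationFraction,
      colocalizationDist = as.integer(colocalizationDist),
      colocalizeTo = colocalizeTo, peakOffset = as.integer(peakOffset),
      peakSigma = peakSigma, peakAmplitudeMean = peakAmplitudeMean,
      backgroundRate = backgroundRate, ctNoiseSd = ctNoiseSd,
      ctReplicates = as.integer(ctReplicates), trueFold = trueFold,
      librarySizes = librarySizes, trueAbundances = trueAbundances,
      nAbundanceGenes = as.integer(nAbundanceGenes))
}

# Uniform random point features over the genome.
.uniformPoints <- function(n, si) {
  len <- GenomeInfoDb::seqlengths(si)
  ci <- sample.int(length(len), n, replace = TRUE, prob = len)
  pos <- floor(stats::runif(n) * len[ci]) + 1L
  ord <- order(ci, pos)
  GRanges(GenomeInfoDb::seqnames(si)[ci][ord],
          IRanges(pos[ord], pos[ord]), seqinfo = si)
}

#' Simulate a genome with genes and feature sets
#'
#' Places non-overlapping tRNA genes and ORFs (strands uniform, lengths
#' uniform in 70-120 bp and 500-2000 bp respectively) on a multi-
#' chromosome genome carrying replication-origin and TAD-boundary point
#' features. `round(colocalizationFraction * nTrna)` tRNAs are planted
#' with their TSS within `colocalizationDist` bp of a feature of the
#' `colocalizeTo` set(s); planted status is recorded in the `planted`
#' metadata column. Deterministic per seed.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `genome` (Seqinfo), `genes` (GRanges with
#'   `gene_id`, `gene_class`, `planted`) and `features` (named list of
#'   width-1 GRanges: `origins`, `tad_boundaries`).
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  withr::with_seed(config@seed, {
    si <- GenomeInfoDb::Seqinfo(
      paste0("chr", utils::as.roman(seq_len(config@nChroms))),
      rep(config@chromLength, config@nChroms))
    len <- GenomeInfoDb::seqlengths(si)
    features <- list(origins = .uniformPoints(config@nOrigins, si),
                     tad_boundaries = .uniformPoints(config@nTadBoundaries,
                                                     si))
    trnaLen <- if (config@nTrna)
      sample(70:120, config@nTrna, replace = TRUE) else integer(0)
    orfLen <- if (config@nOrf)
      sample(500:2000, config@nOrf, replace = TRUE) else integer(0)
    if (sum(trnaLen) + sum(orfLen) > 0.8 * sum(len))
      stop("genome too small to place the requested genes without overlap")
    placedChrom <- character(0)
    placedStart <- integer(0)
    placedEnd <- integer(0)
    overlaps <- function(chrom, s, e) {
      sel <- placedChrom == chrom
      any(placedStart[sel] <= e & placedEnd[sel] >= s)
    }
    place <- function(gl, tssAt = NULL) {
      # tssAt: data.frame(chrom, pos) of admissible TSS anchors, or NULL
      # for uniform placement
      for (try in seq_len(10000L)) {
        st <- if (stats::runif(1) < 0.5) "+" else "-"
        if (is.null(tssAt)) {
          ci <- sample.int(length(len), 1L, prob = len)
          chrom <- names(len)[ci]
          s <- floor(stats::runif(1) * (len[[ci]] - gl + 1L)) + 1L
        } else {
          j <- sample.int(nrow(tssAt), 1L)
          chrom <- tssAt$chrom[j]
          tss <- tssAt$pos[j] +
            sample.int(2L * config@colocalizationDist + 1L, 1L) -
            config@colocalizationDist - 1L
          s <- if (st == "+") tss else tss - gl + 1L
        }
        e <- s + gl - 1L
        if (s < 1L || e > len[[chrom]]) next
        if (overlaps(chrom, s, e)) next
        placedChrom <<- c(placedChrom, chrom)
        placedStart <<- c(placedStart, s)
        placedEnd <<- c(placedEnd, e)
        return(list(chrom = chrom, start = s, end = e, strand = st))
      }
      stop("genome too small to place the requested genes without overlap")
    }
    anchorPool <- switch(config@colocalizeTo,
                         origins = features$origins,
                         tad_boundaries = features$tad_boundaries,
                         both = c(features$origins, features$tad_boundaries))
    anchors <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(anchorPool)),
      pos = start(anchorPool))
    nPlanted <- round(config@colocalizationFraction * config@nTrna)
    if (nPlanted > 0L && nrow(anchors) == 0L)
      stop("cannot plant co-localization without features")
    recs <- vector("list", config@nTrna + config@nOrf)
    for (i in seq_len(config@nTrna))
      recs[[i]] <- place(trnaLen[i],
                         tssAt = if (i <= nPlanted) anchors else NULL)
    for (i in seq_len(config@nOrf))
      recs[[config@nTrna + i]] <- place(orfLen[i])
    ids <- c(sprintf("tRNA%03d", seq_len(config@nTrna)),
             sprintf("ORF%04d", seq_len(config@nOrf)))
    cls <- c(rep("tRNA", config@nTrna), rep("ORF", config@nOrf))
    genes <- geneRanges(ids,
                        vapply(recs, `[[`, character(1), "chrom"),
                        vapply(recs, `[[`, numeric(1), "start"),
                        vapply(recs, `[[`, numeric(1), "end"),
                        vapply(recs, `[[`, character(1), "strand"),
                        cls, si)
    mcols(genes)$planted <- c(seq_len(config@nTrna) <= nPlanted,
                              rep(FALSE, config@nOrf))
    list(genome = si, genes = genes, features = features)
  })
}

#' Simulate a ChIP-exo-style tag track
#'
#' Poisson background tags uniform over the genome plus, for every tRNA
#' gene, a peak of `Poisson(peakAmplitudeMean)` tags at gene-oriented
#' offsets `round(Normal(peakOffset, peakSigma))` from the TSS; each tag
#' lands in the forward or reverse channel with equal probability.
#' Deterministic per seed (component offset +1).
#'
#' @param genes GRanges from [simulateGenome()] (peaks go on `tRNA`
#'   rows).
#' @param config a [SimulationConfig-class].
#' @return a [TagTrack-class].
#' @export
simulateTagTrack <- function(genes, config) {
  stopifnot(is(config, "SimulationConfig"))
  si <- GenomeInfoDb::seqinfo(genes)
  withr::with_seed(config@seed + 1L, {
    len <- GenomeInfoDb::seqlengths(si)
    nbg <- stats::rpois(1L, config@backgroundRate * sum(len))
    ci <- sample.int(length(len), nbg, replace = TRUE, prob = len)
    bgChrom <- names(len)[ci]
    bgPos <- floor(stats::runif(nbg) * len[ci]) + 1L
    trna <- genes[mcols(genes)$gene_class == "tRNA"]
    pkChrom <- character(0); pkPos <- integer(0)
    if (length(trna)) {
      amps <- stats::rpois(length(trna), config@peakAmplitudeMean)
      gi <- rep(seq_along(trna), amps)
      off <- round(stats::rnorm(sum(amps), config@peakOffset,
                                config@peakSigma))
      pos <- tssSites(trna)[gi] + .strandSign(trna)[gi] * off
      chrom <- as.character(GenomeInfoDb::seqnames(trna))[gi]
      inb <- pos >= 1L & pos <= len[chrom]
      pkChrom <- chrom[inb]; pkPos <- as.integer(pos[inb])
    }
    chrom <- c(bgChrom, pkChrom)
    pos <- c(bgPos, pkPos)
    isFwd <- stats::runif(length(pos)) < 0.5
    tagTrack(chrom, pos, as.numeric(isFwd), as.numeric(!isFwd), si)
  })
}

#' Simulate a qPCR Ct table with known fold enrichments
#'
#' Constructs Ct values so that [foldEnrichment()] (efficiency 2)
#' recovers `trueFold` exactly at zero noise -- the IP gene Ct is set to
#' `Ct_IP(TelVIR) - log2(fold)` with flat mock and input -- then
#' perturbs every Ct with `Normal(0, ctNoiseSd)`. One condition (`wt`),
#' `ctReplicates` replicates. Deterministic per seed (component offset
#' +2).
#'
#' @param config a [SimulationConfig-class].
#' @param condition condition label stamped on all rows.
#' @return a [CtTable-class].
#' @export
simulateCt <- function(config, condition = "wt") {
  stopifnot(is(config, "SimulationConfig"))
  if (!length(config@trueFold) || is.null(names(config@trueFold)))
    stop("config@trueFold must be a named vector")
  withr::with_seed(config@seed + 2L, {
    genes <- names(config@trueFold)
    base <- c(IP_tel = 26, mock_gene = 28, mock_tel = 28,
              input_gene = 20, input_tel = 20)
    rows <- list()
    for (r in seq_len(config@ctReplicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_kind = rep(c("IP", "mock", "input"), each = 1L),
        condition = condition, amplicon = "TelVIR", replicate = r,
        ct = c(base[["IP_tel"]], base[["mock_tel"]], base[["input_tel"]]))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_kind = rep(c("IP", "mock", "input"), each = length(genes)),
        condition = condition, amplicon = rep(genes, 3L), replicate = r,
        ct = c(base[["IP_tel"]] - log2(config@trueFold),
               rep(base[["mock_gene"]], length(genes)),
               rep(base[["input_gene"]], length(genes))))
    }
    d <- do.call(rbind, rows)
    d$ct <- d$ct + stats::rnorm(nrow(d), 0, config@ctNoiseSd)
    ctTable(d)
  })
}

#' Simulate a tRNA abundance count table
#'
#' Draws each sample's counts from a multinomial over the true relative
#' abundances at its library size. When `trueAbundances` is empty, a
#' Gamma(2, 1) abundance profile over `nAbundanceGenes` tRNAs is drawn
#' once under the seed. Deterministic per seed (component offset +3).
#'
#' @param config a [SimulationConfig-class].
#' @return list with `counts` (a [CountTable-class]) and `abundances`
#'   (the planted relative abundances, summing to 1).
#' @export
simulateCounts <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  if (!length(config@librarySizes) || is.null(names(config@librarySizes)))
    stop("config@librarySizes must be a named vector")
  withr::with_seed(config@seed + 3L, {
    ab <- config@trueAbundances
    if (!length(ab)) {
      ab <- stats::rgamma(config@nAbundanceGenes, shape = 2, rate = 1)
      names(ab) <- sprintf("tRNA%03d", seq_along(ab))
    }
    ab <- ab / sum(ab)
    m <- vapply(config@librarySizes, function(sz)
      stats::rmultinom(1L, as.integer(sz), ab)[, 1], numeric(length(ab)))
    rownames(m) <- names(ab)
    colnames(m) <- names(config@librarySizes)
    list(counts = countTable(m), abundances = ab)
  })
}
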