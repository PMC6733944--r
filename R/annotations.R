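#' @importFrom GenomicRanges GRanges start end strand mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

GENE_CLASSES <- c("tRNA", "ORF", "other_pol3")

#' Build an annotated gene set
#'
#' Constructs a [GenomicRanges::GRanges] of gene bodies with the metadata
#' columns the rest of the package expects: `gene_id` and `gene_class`
#' (`tRNA`, `ORF` or `other_pol3`). Coordinates are 1-based closed, the
#' Bioconductor convention; the TSS of a `+` gene is its `start` and of a
#' `-` gene its `end`.
#'
#' @param geneId character vector of unique identifiers.
#' @param chrom chromosome names (must exist in `seqinfo`).
#' @param start,end 1-based inclusive gene body coordinates.
#' @param strand `"+"` or `"-"` per gene.
#' @param geneClass one of `"tRNA"`, `"ORF"`, `"other_pol3"` (recycled).
#' @param seqinfo a [GenomeInfoDb::Seqinfo] describing the genome.
#' @return GRanges with `gene_id` and `gene_class` metadata columns.
#' @examples
#' si <- GenomeInfoDb::Seqinfo(c("chrI"), 10000)
#' geneRanges("tA1", "chrI", 500, 600, "+", "tRNA", si)
#' @export
geneRanges <- function(geneId, chrom, start, end, strand, geneClass,
                       seqinfo) {
  geneClass <- rep_len(geneClass, length(geneId))
  if (anyDuplicated(geneId)) stop("gene ids must be unique")
  if (!all(geneClass %in% GENE_CLASSES))
    stop("gene_class must be one of: ", paste(GENE_CLASSES, collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(chrom %in% GenomeInfoDb::seqnames(seqinfo)))
    stop("unknown chromosome(s): ",
         paste(unique(setdiff(chrom, GenomeInfoDb::seqnames(seqinfo))),
               collapse = ", "))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(end < start))
    stop("need 1 <= start <= end")
  len <- GenomeInfoDb::seqlengths(seqinfo)[chrom]
  if (any(end > len)) stop("gene end beyond chromosome length")
  gr <- GRanges(chrom, IRanges(start, end), strand = strand,
                seqinfo = seqinfo)
  mcols(gr) <- DataFrame(gene_id = as.character(geneId),
                         gene_class = geneClass)
  gr
}

#' Transcription start / termination sites
#'
#' The TSS of a `+` strand gene is its start coordinate and of a `-`
#' strand gene its end coordinate; the TTS is the opposite body edge.
#'
#' @param genes GRanges from [geneRanges()].
#' @return integer vector of 1-based positions, one per gene.
#' @export
tssSites <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
}

#' @rdname tssSites
#' @export
ttsSites <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", end(genes), start(genes))
}

#' Signed genomic distance from a point to a feature
#'
#' `point - feature` in genome coordinates: negative means the point lies
#' to the left of the feature. Features are unstranded, so the sign is in
#' genome orientation, not gene orientation. When chromosome vectors are
#' supplied, pairs on different chromosomes get `NA` (no distance).
#'
#' @param point,feature 1-based positions (bp), recycled to equal length.
#' @param pointChrom,featureChrom optional chromosome names per position.
#' @return integer offsets, `NA` where chromosomes differ.
#' @examples
#' signedDistance(9600, 10000)  # -400
#' @export
signedDistance <- function(point, feature, pointChrom = NULL,
                           featureChrom = NULL) {
  d <- as.integer(point) - as.integer(feature)
  if (!is.null(pointChrom) || !is.null(featureChrom)) {
    if (is.null(pointChrom) || is.null(featureChrom))
      stop("supply both chromosome vectors or neither")
    d[pointChrom != featureChrom] <- NA_integer_
  }
  d
}

#' Collapse interval features to point features
#'
#' Feature sets used as proximity reference points (replication origins,
#' TAD boundaries) are stored as width-1 points. Interval-shaped sources
#' (e.g. origin intervals) are reduced to their midpoints,
#' `floor((start + end) / 2)` on 1-based closed coordinates.
#'
#' @param features GRanges (any widths).
#' @param name optional label recorded as `metadata(x)$featureName`.
#' @return GRanges of width-1 points on the same genome.
#' @export
featurePoints <- function(features, name = NULL) {
  mid <- as.integer(floor((start(features) + end(features)) / 2))
  out <- GRanges(GenomeInfoDb::seqnames(features), IRanges(mid, mid),
                 seqinfo = GenomeInfoDb::seqinfo(features))
  if (!is.null(name)) S4Vectors::metadata(out)$featureName <- name
  out
}

#' Genes whose TSS lies within a distance of a feature
#'
#' Retains each gene (once) whose TSS -- or nearest body edge, in
#' `"edge"` mode -- is within `maxDist` bp (closed, i.e. `<=`) of at least
#' one feature point on the same chromosome. This is the operation behind
#' counts such as "genes within 1 kb of TAD boundaries".
#'
#' @param features GRanges of width-1 points (see [featurePoints()]).
#' @param genes GRanges from [geneRanges()].
#' @param maxDist maximum absolute distance in bp (`>= 0`; 0 keeps only
#'   genes whose anchor coincides with a feature).
#' @param mode `"tss"` (default) measures from the TSS; `"edge"` from the
#'   nearest gene-body edge (0 if the feature falls inside the body).
#' @return the retained subset of `genes`.
#' @export
genesWithin <- function(features, genes, maxDist, mode = c("tss", "edge")) {
  mode <- match.arg(mode)
  if (maxDist < 0) stop("maxDist must be >= 0")
  if (length(features) == 0L || length(genes) == 0L)
    return(genes[integer(0)])
  fchr <- as.character(GenomeInfoDb::seqnames(features))
  fpos <- start(features)
  gchr <- as.character(GenomeInfoDb::seqnames(genes))
  keep <- vapply(seq_along(genes), function(i) {
    sel <- fchr == gchr[i]
    if (!any(sel)) return(FALSE)
    if (mode == "tss") {
      d <- abs(tssSites(genes[i]) - fpos[sel])
    } else {
      d <- pmax(0L, pmax(start(genes)[i] - fpos[sel],
                         fpos[sel] - end(genes)[i]))
    }
    any(d <= maxDist)
  }, logical(1))
  genes[keep]
}

#' Read a chromosome-sizes file
#'
#' Two whitespace/tab-delimited columns (no header): chromosome name and
#' length in bp.
#'
#' @param path file path.
#' @return a [GenomeInfoDb::Seqinfo].
#' @export
readChromSizes <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "",
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "integer"))
  if (nrow(d) == 0L) stop("empty chromosome-sizes file: ", path)
  if (anyDuplicated(d$chrom)) stop("duplicate chromosome names in ", path)
  if (any(d$length <= 0L)) stop("chromosome lengths must be > 0")
  GenomeInfoDb::Seqinfo(d$chrom, d$length)
}

#' Write a chromosome-sizes file
#' @param seqinfo a Seqinfo.
#' @param path destination.
#' @export
writeChromSizes <- function(seqinfo, path) {
  utils::write.table(
    data.frame(GenomeInfoDb::seqnames(seqinfo),
               GenomeInfoDb::seqlengths(seqinfo)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a tab-delimited gene annotation table
#'
#' Headered table with columns `gene_id`, `chrom`, `start`, `end`,
#' `strand`, `class`; coordinates are documented as 1-based inclusive (the
#' SGD-export convention) and stored unchanged. Delimiter is auto-detected
#' among tab and comma.
#'
#' @param path file path.
#' @param seqinfo genome the coordinates must fall in.
#' @return GRanges as from [geneRanges()].
#' @export
readGeneTable <- function(path, seqinfo) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand", "class")
  if (!all(need %in% names(d)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (nrow(d) == 0L)
    return(geneRanges(character(0), character(0), integer(0), integer(0),
                      character(0), character(0), seqinfo))
  geneRanges(d$gene_id, d$chrom, d$start, d$end, d$strand, d$class, seqinfo)
}

#' @rdname readGeneTable
#' @param genes GRanges from [geneRanges()].
#' @export
writeGeneTable <- function(genes, path) {
  d <- data.frame(gene_id = mcols(genes)$gene_id,
                  chrom = as.character(GenomeInfoDb::seqnames(genes)),
                  start = start(genes), end = end(genes),
                  strand = as.character(strand(genes)),
                  class = mcols(genes)$gene_class)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a point-feature table
#'
#' Headered two-column table (`chrom`, `pos`; 1-based) of point features
#' such as replication-origin midpoints or TAD boundaries.
#'
#' @param path file path.
#' @param seqinfo genome the positions must fall in.
#' @param name optional feature-set label (see [featurePoints()]).
#' @return GRanges of width-1 points.
#' @export
readFeatureTable <- function(path, seqinfo, name = NULL) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("chrom", "pos") %in% names(d)))
    stop("feature table must have columns: chrom, pos")
  if (!all(d$chrom %in% GenomeInfoDb::seqnames(seqinfo)))
    stop("unknown chromosome(s) in ", path)
  len <- GenomeInfoDb::seqlengths(seqinfo)[d$chrom]
  if (nrow(d) && (any(d$pos < 1L) || any(d$pos > len)))
    stop("feature positions outside chromosome bounds in ", path)
  gr <- GRanges(d$chrom, IRanges(d$pos, d$pos), seqinfo = seqinfo)
  if (!is.null(name)) S4Vectors::metadata(gr)$featureName <- name
  gr
}

#' @rdname readFeatureTable
#' @param features width-1 GRanges to write.
#' @export
writeFeatureTable <- function(features, path) {
  utils::write.table(
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(features)),
               pos = start(features)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write BED6
#'
#' Thin wrappers over [rtracklayer::import.bed()] / `export.bed()`; BED's
#' 0-based half-open coordinates are converted to the internal 1-based
#' closed convention by rtracklayer. The BED `name` field carries the gene
#' id; BED6 has no class column, so a uniform `geneClass` is assigned.
#'
#' @param path file path.
#' @param seqinfo genome the records must fall in.
#' @param geneClass class label assigned to every record.
#' @return GRanges as from [geneRanges()].
#' @export
readBed6 <- function(path, seqinfo, geneClass = "other_pol3") {
  gr <- rtracklayer::import(path, format = "BED")
  ids <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name)
         else sprintf("feature_%04d", seq_along(gr))
  st <- as.character(strand(gr))
  st[st == "*"] <- "+"
  geneRanges(ids, as.character(GenomeInfoDb::seqnames(gr)),
             start(gr), end(gr), st, geneClass, seqinfo)
}

#' @rdname readBed6
#' @param genes GRanges with `gene_id` metadata.
#' @export
writeBed6 <- function(genes, path) {
  gr <- GRanges(GenomeInfoDb::seqnames(genes),
                IRanges(start(genes), end(genes)),
                strand = strand(genes))
  mcols(gr)$name <- mcols(genes)$gene_id
  mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
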