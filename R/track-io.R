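#' @importFrom data.table fread data.table as.data.table setorder :=
NULL

#' Construct a TagTrack from per-position counts
#'
#' @param chrom,pos,fwd,rev parallel vectors: chromosome, 1-based
#'   position, forward-channel count, reverse-channel count. Duplicate
#'   (chrom, pos) rows are summed.
#' @param seqinfo the genome the positions refer to.
#' @return a [TagTrack-class].
#' @export
tagTrack <- function(chrom, pos, fwd, rev, seqinfo) {
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   fwd = as.numeric(fwd), rev = as.numeric(rev))
  if (nrow(dt)) {
    dt <- dt[, list(fwd = sum(fwd), rev = sum(rev)), by = c("chrom", "pos")]
    setorder(dt, chrom, pos)
  }
  dt[, "total" := dt$fwd + dt$rev]
  new("TagTrack", data = as.data.frame(dt), seqinfo = seqinfo)
}

#' Read a processed tag table
#'
#' Headered, tab- or comma-delimited table with columns `chrom`,
#' `position`, `forward_count`, `reverse_count` -- the processed-file
#' dialect of ChIP-exo depositions. Positions are documented as 1-based
#' (`oneBased = FALSE` switches the dialect and shifts on read). Duplicate
#' positions are summed (with a message); malformed rows and unknown
#' chromosomes are rejected with the offending line or name.
#'
#' @param path file path.
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @param oneBased whether positions in the file are 1-based (default) or
#'   0-based.
#' @param columns optional character vector remapping the four expected
#'   column names, in order (chrom, position, forward, reverse).
#' @return a [TagTrack-class].
#' @export
readTagTable <- function(path, genome, oneBased = TRUE,
                         columns = c("chrom", "position",
                                     "forward_count", "reverse_count")) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(columns %in% names(d)))
    stop("tag table must have columns: ", paste(columns, collapse = ", "))
  if (nrow(d) == 0L)
    return(tagTrack(character(0), integer(0), numeric(0), numeric(0),
                    genome))
  chrom <- as.character(d[[columns[1]]])
  posRaw <- d[[columns[2]]]
  fwd <- d[[columns[3]]]
  rev <- d[[columns[4]]]
  bad <- !is.finite(suppressWarnings(as.numeric(posRaw))) |
    !is.finite(suppressWarnings(as.numeric(fwd))) |
    !is.finite(suppressWarnings(as.numeric(rev))) |
    as.numeric(fwd) < 0 | as.numeric(rev) < 0
  if (any(bad))
    stop("malformed tag-table row at line ", which(bad)[1] + 1L,
         " of ", path)
  pos <- as.integer(posRaw) + if (oneBased) 0L else 1L
  unknown <- setdiff(unique(chrom), GenomeInfoDb::seqnames(genome))
  if (length(unknown))
    stop("unknown chromosome(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  len <- GenomeInfoDb::seqlengths(genome)[chrom]
  oob <- pos < 1L | pos > len
  if (any(oob))
    stop("tag-table position outside chromosome bounds at line ",
         which(oob)[1] + 1L, " of ", path)
  if (anyDuplicated(data.frame(chrom, pos)))
    message("duplicate (chrom, position) rows in ", path, ": counts summed")
  tagTrack(chrom, pos, as.numeric(fwd), as.numeric(rev), genome)
}

#' @rdname readTagTable
#' @param track a [TagTrack-class] to write.
#' @export
writeTagTable <- function(track, path, oneBased = TRUE) {
  d <- track@data
  out <- data.frame(chrom = d$chrom,
                    position = d$pos - if (oneBased) 0L else 1L,
                    forward_count = d$fwd, reverse_count = d$rev)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Sum the forward and reverse channels
#'
#' Returns a track whose channels are replaced by their sum placed in the
#' forward channel, making the collapsed channel authoritative -- the form
#' the genome-wide analyses consume ("the counts for forward and reverse
#' tags were summed"). Totals are unchanged.
#'
#' @param track a [TagTrack-class].
#' @return a [TagTrack-class] with `fwd = fwd + rev`, `rev = 0`.
#' @export
collapseTags <- function(track) {
  d <- track@data
  tagTrack(d$chrom, d$pos, d$fwd + d$rev, rep(0, nrow(d)), track@seqinfo)
}

#' Write per-position values as bedGraph
#'
#' Emits 0-based half-open bedGraph records, merging runs of adjacent
#' positions with equal value. Input rows are sorted before writing.
#'
#' @param track a [TagTrack-class] (the collapsed channel is written).
#' @param path destination (`.bedgraph`).
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  d <- track@data[order(track@data$chrom, track@data$pos), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  if (nrow(d) == 0L) return(invisible(path))
  # run-length merge: same chrom, consecutive positions, equal value
  newRun <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                d$pos[-1] != d$pos[-nrow(d)] + 1L |
                d$total[-1] != d$total[-nrow(d)])
  runId <- cumsum(newRun)
  first <- !duplicated(runId)
  last <- !duplicated(runId, fromLast = TRUE)
  recs <- data.frame(chrom = d$chrom[first],
                     start = d$pos[first] - 1L,   # to 0-based
                     end = d$pos[last],           # half-open
                     value = d$total[first])
  utils::write.table(format(recs, scientific = FALSE, trim = TRUE), con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file back into a TagTrack
#'
#' Expands each record to per-position values in the collapsed channel
#' (forward channel carries the value; strand channels are not
#' represented in bedGraph).
#'
#' @param path bedGraph file.
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @return a [TagTrack-class].
#' @export
readBedGraph <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L)
    return(tagTrack(character(0), integer(0), numeric(0), numeric(0),
                    genome))
  n <- GenomicRanges::width(gr)
  chrom <- rep(as.character(GenomeInfoDb::seqnames(gr)), n)
  pos <- unlist(lapply(seq_along(gr), function(i)
    seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])))
  val <- rep(S4Vectors::mcols(gr)$score, n)
  tagTrack(chrom, pos, val, numeric(length(val)), genome)
}

#' Read a qPCR Ct table
#'
#' Headered tab/CSV with columns `sample_kind` (IP, mock or input),
#' `condition`, `amplicon`, `replicate`, `ct`. Validated on read: every
#' (sample kind, condition, replicate) must include a `TelVIR` control
#' row, and Ct values must be finite and positive.
#'
#' @param path file path.
#' @return a [CtTable-class].
#' @export
readCtTable <- function(path) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("sample_kind", "condition", "amplicon", "replicate", "ct")
  if (!all(need %in% names(d)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  ctTable(d)
}

#' @rdname readCtTable
#' @param data data.frame in the same layout.
#' @export
ctTable <- function(data) {
  data$sample_kind <- as.character(data$sample_kind)
  data$condition <- as.character(data$condition)
  data$amplicon <- as.character(data$amplicon)
  new("CtTable", data = data)
}

#' @rdname readCtTable
#' @param ct a [CtTable-class] to write.
#' @export
writeCtTable <- function(ct, path) {
  utils::write.table(ct@data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an abundance count table
#'
#' Headered tab/CSV; first column holds row identifiers (tRNA ids),
#' remaining columns are per-sample non-negative integer counts.
#'
#' @param path file path.
#' @return a [CountTable-class].
#' @export
readCountTable <- function(path) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(d) < 2L) stop("count table needs an id column plus >= 1 sample")
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("count columns must be numeric")
  if (any(m < 0)) stop("negative counts in ", path)
  rownames(m) <- ids
  countTable(m)
}

#' @rdname readCountTable
#' @param counts named non-negative integer matrix.
#' @export
countTable <- function(counts) new("CountTable", counts = counts)

#' @rdname readCountTable
#' @param x a [CountTable-class] to write.
#' @export
writeCountTable <- function(x, path) {
  d <- data.frame(id = rownames(x@counts), x@counts, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
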