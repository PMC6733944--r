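# The ChIP-qPCR "fold enrichment method", condition ratios, replicate
# significance testing, blot band normalization and count-table
# normalization.

.getCt <- function(ct, kind, condition, amplicon, replicate) {
  d <- ct@data
  sel <- d$sample_kind == kind & d$condition == condition &
    d$amplicon == amplicon & d$replicate == replicate
  if (sum(sel) == 0L)
    stop(sprintf("missing Ct: %s / %s / %s / replicate %s",
                 kind, condition, amplicon, replicate))
  if (sum(sel) > 1L)
    stop(sprintf("multiple Ct rows: %s / %s / %s / replicate %s",
                 kind, condition, amplicon, replicate))
  d$ct[sel]
}

#' ChIP-qPCR fold enrichment (double-delta-Ct)
#'
#' The fold enrichment method: Ct values from the ChIP (IP) and mock
#' samples are first normalized against the TelVIR control region, then
#' against the input, and the IP enrichment is expressed relative to the
#' mock. With `dCt_s = Ct_s(gene) - Ct_s(TelVIR)` for sample kind `s`,
#'
#' \deqn{FE = \frac{E^{-(dCt_{IP} - dCt_{input})}}
#'                 {E^{-(dCt_{mock} - dCt_{input})}}}
#'
#' where `E` is the amplification efficiency (2 = perfect doubling).
#' Adding a constant to every Ct of one sample kind leaves the result
#' unchanged.
#'
#' @param ct a [CtTable-class].
#' @param gene amplicon id (not `TelVIR`).
#' @param condition condition label.
#' @param replicate replicate index.
#' @param efficiency amplification efficiency per cycle (`> 0`).
#' @return positive fold enrichment.
#' @export
foldEnrichment <- function(ct, gene, condition, replicate,
                           efficiency = 2.0) {
  if (!is.numeric(efficiency) || efficiency <= 0)
    stop("efficiency must be > 0")
  dIP <- .getCt(ct, "IP", condition, gene, replicate) -
    .getCt(ct, "IP", condition, "TelVIR", replicate)
  dMock <- .getCt(ct, "mock", condition, gene, replicate) -
    .getCt(ct, "mock", condition, "TelVIR", replicate)
  dInput <- .getCt(ct, "input", condition, gene, replicate) -
    .getCt(ct, "input", condition, "TelVIR", replicate)
  efficiency^(-(dIP - dInput)) / efficiency^(-(dMock - dInput))
}

#' Per-gene enrichment estimates with replicate aggregation
#'
#' Computes [foldEnrichment()] for every (gene, condition, replicate)
#' present, aggregates replicates by arithmetic mean with min/max scatter
#' (and SD), and -- when a reference condition is named -- attaches a
#' two-tailed pooled-variance t-test p-value versus the reference and a
#' significance flag at 0.05 (the non-significant dot convention).
#'
#' @param ct a [CtTable-class].
#' @param efficiency amplification efficiency.
#' @param reference optional condition to test each other condition
#'   against, gene by gene.
#' @return data.frame with columns `gene_id`, `condition`, `n`, `mean`,
#'   `min`, `max`, `sd`, and (with a reference) `p_value`,
#'   `significant`.
#' @export
enrichmentEstimates <- function(ct, efficiency = 2.0, reference = NULL) {
  d <- ct@data
  ip <- d[d$sample_kind == "IP" & d$amplicon != "TelVIR", , drop = FALSE]
  combos <- unique(ip[c("amplicon", "condition")])
  reps <- lapply(seq_len(nrow(combos)), function(i) {
    g <- combos$amplicon[i]; cond <- combos$condition[i]
    rr <- sort(unique(ip$replicate[ip$amplicon == g &
                                     ip$condition == cond]))
    vapply(rr, function(r) foldEnrichment(ct, g, cond, r, efficiency),
           numeric(1))
  })
  out <- data.frame(gene_id = combos$amplicon,
                    condition = combos$condition,
                    n = vapply(reps, length, integer(1)),
                    mean = vapply(reps, mean, numeric(1)),
                    min = vapply(reps, min, numeric(1)),
                    max = vapply(reps, max, numeric(1)),
                    sd = vapply(reps, stats::sd, numeric(1)))
  if (!is.null(reference)) {
    if (!reference %in% out$condition)
      stop("reference condition not present: ", reference)
    out$p_value <- NA_real_
    for (i in seq_len(nrow(out))) {
      if (out$condition[i] == reference) next
      j <- which(out$gene_id == out$gene_id[i] &
                   out$condition == reference)
      if (!length(j)) next
      out$p_value[i] <- replicateTTest(reps[[i]], reps[[j]])$pValue
    }
    out$significant <- !is.na(out$p_value) & out$p_value <= 0.05
  }
  out
}

#' Ratio of enrichment between two conditions
#'
#' Treated-over-untreated mean fold enrichment per gene; 1.0 denotes no
#' change.
#'
#' @param treated,untreated data.frames from [enrichmentEstimates()] (or
#'   any with `gene_id` and `mean`).
#' @return data.frame with `gene_id` and `ratio`.
#' @export
conditionRatio <- function(treated, untreated) {
  m <- match(treated$gene_id, untreated$gene_id)
  if (anyNA(m))
    stop("no untreated estimate for gene(s): ",
         paste(treated$gene_id[is.na(m)], collapse = ", "))
  if (any(untreated$mean[m] <= 0)) stop("untreated means must be > 0")
  data.frame(gene_id = treated$gene_id,
             ratio = treated$mean / untreated$mean[m])
}

#' Two-tailed unpaired Student's t-test between replicate sets
#'
#' The replicate significance test used throughout: pooled-variance
#' Student's t (shared core with [proximalDistalTest()]), symmetric in
#' its arguments. Degenerate inputs (zero variance in both groups) give
#' p = 1 when the means agree and an error otherwise.
#'
#' @param valuesA,valuesB numeric vectors (`>= 2` values each).
#' @param welch use Welch's unequal-variance variant.
#' @return list with `statistic`, `df`, `pValue`.
#' @export
replicateTTest <- function(valuesA, valuesB, welch = FALSE) {
  .tTestCore(valuesA, valuesB, welch = welch)
}

#' Band intensity normalization
#'
#' Target band intensity divided by the loading-control band intensity
#' (e.g. a transcript over U4, or a protein over histone H3); invariant
#' under a common scanner gain.
#'
#' @param targetIntensity,controlIntensity numeric (control `> 0`).
#' @return normalized level(s).
#' @export
bandRatio <- function(targetIntensity, controlIntensity) {
  if (any(controlIntensity <= 0)) stop("control intensity must be > 0")
  targetIntensity / controlIntensity
}

#' Library-size normalization and log2 comparison of count tables
#'
#' Per-million scaling (`count / column_sum * 1e6`) followed by
#' `log2(value + pseudocount)`; optionally a per-row fold change between
#' two named samples, `normalized[, b] / normalized[, a]` for
#' `contrast = c(a, b)`. Rank order within each sample is preserved.
#'
#' @param counts a [CountTable-class] or named count matrix.
#' @param method only `"per_million"` is defined.
#' @param pseudocount added before the log transform.
#' @param contrast optional length-2 character vector of sample names.
#' @return a [NormalizedAbundance-class].
#' @export
normalizeCounts <- function(counts, method = "per_million",
                            pseudocount = 1, contrast = NULL) {
  method <- match.arg(method, "per_million")
  m <- if (is(counts, "CountTable")) counts@counts else counts
  cs <- colSums(m)
  if (any(cs <= 0))
    stop("zero-sum column(s) cannot be normalized: ",
         paste(colnames(m)[cs <= 0], collapse = ", "))
  norm <- sweep(m, 2L, cs, "/") * 1e6
  fc <- data.frame(id = character(0), fold_change = numeric(0))
  if (!is.null(contrast)) {
    if (length(contrast) != 2L || !all(contrast %in% colnames(m)))
      stop("contrast must name two columns of the count table")
    denom <- norm[, contrast[1]]
    if (any(denom == 0))
      fcVals <- ifelse(denom == 0, NA_real_, norm[, contrast[2]] / denom)
    else fcVals <- norm[, contrast[2]] / denom
    fc <- data.frame(id = rownames(m), fold_change = unname(fcVals))
  }
  new("NormalizedAbundance", normalized = norm,
      log2Values = log2(norm + pseudocount),
      pseudocount = pseudocount, method = method, foldChanges = fc)
}
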