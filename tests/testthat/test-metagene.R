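constTrack <- function(si, value = 3) {
  len <- GenomeInfoDb::seqlengths(si)
  chrom <- rep(GenomeInfoDb::seqnames(si), len)
  pos <- unlist(lapply(len, seq_len))
  tagTrack(chrom, pos, rep(value, length(pos)), rep(0, length(pos)), si)
}

test_that("a constant field profiles flat at the constant", {
  si <- si1(400L)
  tr <- constTrack(si, 3)
  genes <- mkGenes(c("chrI", "chrI"), c(150, 210), c(170, 260),
                   c("+", "-"), si = si)
  p <- computeProfile(tr, genes, flank = 50)
  expect_true(all(profileValues(p) == 3))
  expect_identical(p@nRegions, 2L)
})

test_that("opposite-strand genes average with orientation flip", {
  si <- si1(40L)
  # hand-built track: count equals position index, so the oriented value
  # at offset k is (tssA + k) for the + gene and (tssB - k) for the -
  tr <- mkTrack(rep("chrI", 40), 1:40, fwd = as.numeric(1:40), si = si)
  genes <- mkGenes(c("chrI", "chrI"), c(15, 20), c(18, 25), c("+", "-"),
                   si = si)
  p <- computeProfile(tr, genes, flank = 5)
  # + gene TSS 15, - gene TSS 25; mean at offset k = ((15+k)+(25-k))/2 = 20
  expect_equal(profileValues(p), rep(20, 11))
  m <- computeProfile(tr, genes, flank = 5, keepMatrix = TRUE)@perGeneMatrix
  expect_equal(unname(m[1, ]), as.numeric(10:20))
  expect_equal(unname(m[2, ]), as.numeric(30:20))
})

test_that("profile equals the naive double loop on random fixtures", {
  si <- si2(c(3000L, 3000L))
  withr::with_seed(21, {
    pos <- sample.int(3000, 700)
    tr <- mkTrack(sample(c("chrI", "chrII"), 700, TRUE), pos,
                  rpois(700, 2), rpois(700, 1), si)
    gs <- sample(200:2500, 12)
    genes <- mkGenes(sample(c("chrI", "chrII"), 12, TRUE), gs, gs + 90,
                     sample(c("+", "-"), 12, TRUE), si = si)
  })
  p <- computeProfile(tr, genes, flank = 60)
  expect_equal(profileValues(p), bruteProfile(tr, genes, 60),
               tolerance = 1e-12)
})

test_that("genome reflection leaves the profile identical", {
  si <- si2(c(5000L, 8000L))
  withr::with_seed(13, {
    pos <- sample.int(5000, 900)
    tr <- mkTrack(sample(c("chrI", "chrII"), 900, TRUE), pos,
                  rpois(900, 2), rpois(900, 1), si)
    gs <- sample(500:4000, 15)
    genes <- mkGenes(sample(c("chrI", "chrII"), 15, TRUE), gs, gs + 100,
                     sample(c("+", "-"), 15, TRUE), si = si)
  })
  p1 <- profileValues(computeProfile(tr, genes, flank = 100))
  p2 <- profileValues(computeProfile(reflectTrack(tr),
                                     reflectGenes(genes), flank = 100))
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("out-of-bounds windows exclude genes with a message", {
  si <- si1(1000L)
  tr <- mkTrack("chrI", 500, 2, si = si)
  genes <- mkGenes(c("chrI", "chrI"), c(30, 500), c(60, 540), c("+", "+"),
                   si = si)
  expect_message(p <- computeProfile(tr, genes, flank = 100), "excluded")
  expect_identical(p@nRegions, 1L)
  expect_error(suppressMessages(computeProfile(tr, genes, flank = 600)),
               "all genes excluded")
})

test_that("pol II gene-end filter removes doubly-flanked tRNAs", {
  si <- si1(50000L)
  # tRNA at 10000-10100; ORF end 200 bp upstream, ORF start 250 bp down
  trna <- mkGenes("chrI", 10000, 10100, "+", si = si)
  orfs <- mkGenes(c("chrI", "chrI"), c(9000, 10350), c(9800, 11000),
                  c("+", "+"), class = "ORF", si = si)
  expect_length(filterFlankedGenes(trna, orfs, window = 300), 0L)
  # nearest ends at 400 bp on both sides: retained
  farOrfs <- mkGenes(c("chrI", "chrI"), c(9000, 10500), c(9600, 11000),
                     c("+", "+"), class = "ORF", si = si)
  expect_length(filterFlankedGenes(trna, farOrfs, window = 300), 1L)
  # window 0 retains every tRNA unless an end touches the body
  expect_length(filterFlankedGenes(trna, orfs, window = 0), 1L)
  touching <- mkGenes("chrI", 5000, 10000, "+", class = "ORF", si = si)
  expect_length(filterFlankedGenes(trna, touching, window = 0,
                                   mode = "either_side"), 0L)
})

test_that("both_sides filtering retains a superset of either_side", {
  si <- si2(c(60000L, 60000L))
  withr::with_seed(31, {
    ts <- sample(2000:58000, 40)
    trnas <- mkGenes(sample(c("chrI", "chrII"), 40, TRUE), ts, ts + 90,
                     sample(c("+", "-"), 40, TRUE), si = si)
    os <- sample(1000:55000, 60)
    orfs <- mkGenes(sample(c("chrI", "chrII"), 60, TRUE), os, os + 1500,
                    sample(c("+", "-"), 60, TRUE), class = "ORF", si = si,
                    ids = sprintf("orf%03d", 1:60))
  })
  both <- filterFlankedGenes(trnas, orfs, 300, "both_sides")
  either <- filterFlankedGenes(trnas, orfs, 300, "either_side")
  expect_true(all(S4Vectors::mcols(either)$gene_id %in%
                    S4Vectors::mcols(both)$gene_id))
  # and both modes match the brute-force oracle
  expect_identical(S4Vectors::mcols(both)$gene_id,
                   S4Vectors::mcols(
                     bruteFilterFlanked(trnas, orfs, 300, "both_sides"))$gene_id)
  expect_identical(S4Vectors::mcols(either)$gene_id,
                   S4Vectors::mcols(
                     bruteFilterFlanked(trnas, orfs, 300, "either_side"))$gene_id)
})

test_that("ORF density assigns proximal ends to gene-oriented windows", {
  si <- si1(50000L)
  trna <- mkGenes("chrI", 10000, 10100, "+", si = si)
  expect_true(all(orfDensity(trna, trna[0])$count == 0))
  # same-strand ORF starting 150 bp downstream of the tRNA end
  orf <- mkGenes("chrI", 10250, 11500, "+", class = "ORF", si = si)
  d <- orfDensity(trna, orf, step = 100, span = 1000)
  down <- d[d$side == "downstream", ]
  expect_identical(down$count[down$dist_lo == 100], 1L)
  expect_identical(sum(d$count), 1L)
  # opposite strand not counted in same-strand mode, counted otherwise
  orfMinus <- mkGenes("chrI", 10250, 11500, "-", class = "ORF", si = si)
  expect_identical(sum(orfDensity(trna, orfMinus)$count), 0L)
  expect_identical(sum(orfDensity(trna, orfMinus, sameStrand = FALSE)$count),
                   1L)
})

test_that("ORF density totals match a brute-force nested loop", {
  si <- si2(c(80000L, 80000L))
  withr::with_seed(41, {
    ts <- sample(3000:75000, 30)
    trnas <- mkGenes(sample(c("chrI", "chrII"), 30, TRUE), ts, ts + 90,
                     sample(c("+", "-"), 30, TRUE), si = si)
    os <- sample(1500:76000, 100)
    orfs <- mkGenes(sample(c("chrI", "chrII"), 100, TRUE), os, os + 900,
                    sample(c("+", "-"), 100, TRUE), class = "ORF", si = si,
                    ids = sprintf("orf%03d", 1:100))
  })
  got <- orfDensity(trnas, orfs, step = 100, span = 1000)
  # independent nested-loop count, and window-sum conservation
  brute <- matrix(0L, 2, 10)  # rows: upstream, downstream
  pairsInSpan <- 0L
  for (i in seq_along(trnas)) for (j in seq_along(orfs)) {
    if (as.character(GenomeInfoDb::seqnames(trnas))[i] !=
        as.character(GenomeInfoDb::seqnames(orfs))[j]) next
    if (as.character(GenomicRanges::strand(trnas))[i] !=
        as.character(GenomicRanges::strand(orfs))[j]) next
    ts <- GenomicRanges::start(trnas)[i]; te <- GenomicRanges::end(trnas)[i]
    os1 <- GenomicRanges::start(orfs)[j]; oe <- GenomicRanges::end(orfs)[j]
    if (os1 > te) { dg <- os1 - te; sideRight <- TRUE }
    else if (oe < ts) { dg <- ts - oe; sideRight <- FALSE }
    else next
    plus <- as.character(GenomicRanges::strand(trnas))[i] == "+"
    down <- (plus && sideRight) || (!plus && !sideRight)
    if (dg < 1000) {
      brute[if (down) 2 else 1, dg %/% 100 + 1] <-
        brute[if (down) 2 else 1, dg %/% 100 + 1] + 1L
      pairsInSpan <- pairsInSpan + 1L
    }
  }
  expect_identical(got$count[got$side == "upstream"], brute[1, ])
  expect_identical(got$count[got$side == "downstream"], brute[2, ])
  expect_identical(sum(got$count), pairsInSpan)
})

test_that("heatmap rows pool flanks and rescale bodies", {
  si <- si1(400L)
  tr <- constTrack(si, 2.5)
  genes <- mkGenes("chrI", 150, 249, "+", si = si)
  hm <- heatmapMatrix(tr, genes, flank = 50, bodyBins = 10, binSize = 10)
  expect_true(all(hm@values == 2.5))

  # single 100-bp gene over a hand-built ramp track: pooled means
  ramp <- mkTrack(rep("chrI", 400), 1:400, as.numeric(1:400), si = si)
  hm2 <- heatmapMatrix(ramp, genes, flank = 50, bodyBins = 10,
                       binSize = 10, sortRows = FALSE)
  v <- as.numeric(1:400)
  expectRow <- c(vapply(0:4, function(b) mean(v[99 + b * 10 + 1:10]), 0),
                 vapply(0:9, function(b) mean(v[149 + b * 10 + 1:10]), 0),
                 vapply(0:4, function(b) mean(v[249 + b * 10 + 1:10]), 0))
  expect_equal(unname(hm2@values[1, ]), expectRow)

  # genes shorter than bodyBins interpolate (with a message)
  short <- mkGenes("chrI", 200, 205, "+", si = si)
  expect_message(hm3 <- heatmapMatrix(ramp, short, flank = 50,
                                      bodyBins = 10, binSize = 10),
                 "interpolated")
  expect_identical(ncol(hm3@values), 20L)
})

test_that("heatmap flank columns agree with the TSS/TTS profiles", {
  si <- si1(5000L)
  withr::with_seed(51, {
    tr <- mkTrack(rep("chrI", 1200), sample.int(5000, 1200),
                  rpois(1200, 3), si = si)
    gs <- sample(1200:3500, 8)
    genes <- mkGenes(rep("chrI", 8), gs, gs + 199,
                     sample(c("+", "-"), 8, TRUE), si = si)
  })
  flank <- 100L; binSize <- 10L
  hm <- heatmapMatrix(tr, genes, flank = flank, bodyBins = 20,
                      binSize = binSize, sortRows = FALSE)
  profTss <- profileValues(computeProfile(tr, genes, flank = flank))
  # upstream offsets -flank..-1 pooled in binSize groups
  upstream <- profTss[seq_len(flank)]
  pooled <- colMeans(matrix(upstream, nrow = binSize))
  expect_equal(unname(colMeans(hm@values[, 1:(flank / binSize)])), pooled,
               tolerance = 1e-9)
  profTts <- profileValues(computeProfile(tr, genes, flank = flank,
                                          anchor = "TTS"))
  downstream <- profTts[flank + 1L + seq_len(flank)]
  pooledDown <- colMeans(matrix(downstream, nrow = binSize))
  expect_equal(unname(colMeans(hm@values[, 30 + 1:(flank / binSize)])),
               pooledDown, tolerance = 1e-9)
})

test_that("windowed mean occupancy is strand-aware and truncates at ends", {
  si <- si1(1000L)
  tr <- constTrack(si, 4)
  g <- mkGenes("chrI", 500, 540, "+", si = si)
  expect_equal(meanWindowOccupancy(tr, g, -205, 155), 4)

  # hand-built 10-position track, window [-2, +2]
  hand <- mkTrack("chrI", 496:505, as.numeric(1:10), si = si)
  expect_equal(meanWindowOccupancy(hand, g, -2, 2), mean(3:7))

  # minus-strand gene equals plus-strand gene on the mirror-image track
  gm <- reflectGenes(g)
  expect_equal(meanWindowOccupancy(reflectTrack(hand), gm, -2, 2),
               meanWindowOccupancy(hand, g, -2, 2))

  # truncation at the chromosome start
  edge <- mkGenes("chrI", 3, 40, "+", si = si)
  expect_message(v <- meanWindowOccupancy(tr, edge, -10, 5), "truncated")
  expect_equal(v, 4)
})

test_that("pearsonR matches the textbook formula and flags degenerate input", {
  expect_equal(pearsonR(1:5, 1:5), 1.0)
  expect_equal(pearsonR(1:5, -(1:5)), -1.0)
  xs <- c(1, 2, 3, 4); ys <- c(1, 3, 2, 5)
  hand <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  expect_equal(pearsonR(xs, ys), hand, tolerance = 1e-12)
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearsonR(1:2, 1:2), "at least 3")
})
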