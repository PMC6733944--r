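test_that("bin assignment follows the half-open signed-distance convention", {
  si <- si1(50000L)
  feat <- mkPoints("chrI", 10000, si)
  b <- relativeBinCounts(data.frame(chrom = "chrI", pos = 9600),
                         feat, binSize = 1000, maxDist = 3000)
  m <- binCounts(b)
  expect_equal(sum(m), 1)
  expect_equal(unname(m[1, ]), c(0, 0, 1, 0, 0, 0))  # bin [-1000, 0)

  # empty points give a zero matrix; empty features an error
  empty <- relativeBinCounts(data.frame(chrom = character(0),
                                        pos = integer(0)),
                             feat, 1000, 3000)
  expect_true(all(binCounts(empty) == 0))
  expect_error(relativeBinCounts(data.frame(chrom = "chrI", pos = 1),
                                 feat[0], 1000, 3000), "non-empty")

  # distance 0 falls in the first non-negative bin
  b0 <- relativeBinCounts(data.frame(chrom = "chrI", pos = 10000),
                          feat, 1000, 3000)
  expect_equal(unname(binCounts(b0)[1, ]), c(0, 0, 0, 1, 0, 0))
})

test_that("binning matches the brute-force double loop on random fixtures", {
  si <- si2(c(100000L, 100000L))
  withr::with_seed(61, {
    feat <- mkPoints(sample(c("chrI", "chrII"), 20, TRUE),
                     sample.int(100000, 20), si)
    pts <- data.frame(chrom = sample(c("chrI", "chrII"), 500, TRUE),
                      pos = sample.int(100000, 500),
                      weight = rpois(500, 2) + 1)
  })
  got <- binCounts(relativeBinCounts(pts, feat, 1000, 5000))
  expect_equal(unname(got), bruteBinCounts(pts, feat, 1000, 5000))
})

test_that("total mass is conserved for well-separated features", {
  si <- si2(c(10000L, 10000L))
  feat <- mkPoints(c("chrI", "chrII"), c(5000, 5000), si)
  withr::with_seed(71, {
    pts <- data.frame(chrom = sample(c("chrI", "chrII"), 300, TRUE),
                      pos = sample.int(10000, 300), weight = rpois(300, 3))
  })
  b <- relativeBinCounts(pts, feat, binSize = 1000, maxDist = 10000)
  expect_equal(sum(binCounts(b)), sum(pts$weight))
})

test_that("reflection reverses rows and preserves the test outcome", {
  si <- si2(c(50000L, 50000L))
  withr::with_seed(81, {
    feat <- mkPoints(sample(c("chrI", "chrII"), 10, TRUE),
                     sample(10000:40000, 10), si)
    pts <- data.frame(chrom = sample(c("chrI", "chrII"), 400, TRUE),
                      pos = sample(5000:45000, 400), weight = 1)
  })
  b <- relativeBinCounts(pts, feat, 1000, 3000)
  ptsR <- data.frame(chrom = pts$chrom,
                     pos = GenomeInfoDb::seqlengths(si)[pts$chrom] + 1 -
                       pts$pos, weight = 1)
  bR <- relativeBinCounts(ptsR, reflectPoints(feat), 1000, 3000)
  # rows reverse up to the half-open edge; avoid edge-exact points above
  expect_equal(unname(binCounts(bR)),
               unname(binCounts(b))[, ncol(binCounts(b)):1])
  t1 <- proximalDistalTest(b, 500, 2500)
  t2 <- proximalDistalTest(bR, 500, 2500)
  expect_equal(t1@statistic, t2@statistic, tolerance = 1e-9)
  expect_equal(t1@pValue, t2@pValue, tolerance = 1e-9)
})

test_that("curve normalization rescales without touching counts", {
  si <- si1(50000L)
  feat <- mkPoints("chrI", c(10000, 30000), si)
  pts <- data.frame(chrom = "chrI", pos = c(9600, 9700, 30100))
  b <- relativeBinCounts(pts, feat, 1000, 3000)
  n <- normalizeCurve(b, 2)
  expect_equal(binCurve(n), binCurve(b) / 2)
  expect_identical(binCounts(n), binCounts(b))
  expect_equal(binCurve(normalizeCurve(b, 1)), binCurve(b))
  # inverse recovers the original curve
  expect_equal(binCurve(normalizeCurve(b, 7)) * 7, binCurve(b),
               tolerance = 1e-12)
  expect_error(normalizeCurve(b, 0), "positive")
})

test_that("proximal/distal t-test reproduces the closed form", {
  si <- si1(100000L)
  # craft a binned object with known per-feature vectors: proximal bins
  # hold (2, 4) and distal bins (1, 1) across two features
  feat <- mkPoints("chrI", c(20000, 60000), si)
  mkB <- function(prox, dist) {
    b <- relativeBinCounts(data.frame(chrom = character(0),
                                      pos = integer(0)),
                           feat, 1000, 3000)
    counts <- binCounts(b)
    counts[, 3:4] <- cbind(prox, prox)   # bins [-1000,0) and [0,1000)
    counts[, c(1, 6)] <- cbind(dist, dist)
    initialize(b, counts = counts)
  }
  r <- proximalDistalTest(mkB(c(2, 4), c(1, 1)), 500, 2500)
  expect_equal(r@statistic, 2.0, tolerance = 1e-12)
  expect_equal(r@df, 2)
  expect_equal(r@pValue, 2 * stats::pt(-2, 2), tolerance = 1e-12)
  expect_equal(r@proximalVector, c(2, 4))
  expect_equal(r@distalVector, c(1, 1))

  # equal means with shared values give t = 0, p = 1
  feat3 <- mkPoints("chrI", c(20000, 50000, 80000), si)
  b3 <- relativeBinCounts(data.frame(chrom = character(0),
                                     pos = integer(0)), feat3, 1000, 3000)
  c3 <- binCounts(b3)
  c3[, 3:4] <- cbind(c(1, 2, 3), c(1, 2, 3))
  c3[, c(1, 6)] <- cbind(c(2, 1, 3), c(2, 1, 3))
  r3 <- proximalDistalTest(initialize(b3, counts = c3), 500, 2500)
  expect_equal(r3@statistic, 0)
  expect_equal(r3@pValue, 1)

  # zero variance with unequal means is a degenerate error
  cz <- binCounts(b3)
  cz[, 3:4] <- 2; cz[, c(1, 6)] <- 1
  expect_error(proximalDistalTest(initialize(b3, counts = cz), 500, 2500),
               "degenerate")
})

test_that("t-test p-value agrees with a permutation null", {
  si <- si1(2000000L)
  withr::with_seed(91, {
    feat <- mkPoints("chrI", seq(40000, 1960000, length.out = 30) +
                       sample(-500:500, 30, TRUE), si)
    pts <- data.frame(chrom = "chrI", pos = sample.int(2000000, 1500),
                      weight = 1)
  })
  b <- relativeBinCounts(pts, feat, 1000, 3000)
  r <- proximalDistalTest(b, 500, 2500)
  pPerm <- permutationP(r@proximalVector, r@distalVector, B = 10000)
  expect_lt(abs(r@pValue - pPerm), 0.05)
})

test_that("distal 'beyond' mode widens the distal bin set", {
  si <- si1(50000L)
  feat <- mkPoints("chrI", c(10000, 30000), si)
  withr::with_seed(101, {
    pts <- data.frame(chrom = "chrI", pos = sample.int(50000, 400),
                      weight = 1)
  })
  b <- relativeBinCounts(pts, feat, 1000, 6000)
  pair <- proximalDistalTest(b, 1500, 5000, distalMode = "pair")
  beyond <- proximalDistalTest(b, 1500, 5000, distalMode = "beyond")
  expect_equal(length(pair@distalVector), 2L)
  # beyond-mode distal means average 2 bins (|d| in [5,6) kb) per side
  edges <- b@binEdges
  lo <- head(edges, -1); hi <- tail(edges, -1)
  nBeyond <- sum(hi <= -5000 | lo >= 5000)
  expect_equal(nBeyond, 2L)
  expect_s4_class(beyond, "ProximityTestResult")
  expect_error(proximalDistalTest(b, 5000, 3000), "overlap")
})

test_that("end-to-end proximity analysis is deterministic and complete", {
  cfg <- simulationConfig(seed = 123, colocalizationFraction = 0.4)
  sim <- simulateGenome(cfg)
  track <- simulateTagTrack(sim$genes, cfg)
  rep1 <- runProximityAnalysis(sim$genes, sim$features, track = track)
  rep2 <- runProximityAnalysis(sim$genes, sim$features, track = track)
  expect_identical(rep1, rep2)
  for (fs in c("origins", "tad_boundaries")) {
    expect_setequal(rep1[[fs]]$tests$signal, c("trna", "orf", "tags"))
    expect_true(all(rep1[[fs]]$tests$p >= 0 & rep1[[fs]]$tests$p <= 1))
    expect_setequal(unique(rep1[[fs]]$curves$signal),
                    c("trna", "orf", "tags"))
  }
  # planted tRNA co-localization to TAD boundaries is detected
  expect_lt(rep1$tad_boundaries$tests$p[
    rep1$tad_boundaries$tests$signal == "trna"], 0.01)
})
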