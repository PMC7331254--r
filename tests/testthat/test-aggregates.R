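pointAnchors <- function(chrom, bins, grid) {
  bs <- binSize(grid)
  pos <- (bins - 1) * bs + floor(bs / 2)
  GRanges(chrom, IRanges(start = pos, end = pos + 1))
}

test_that("PE-SCAn windows match brute-force extraction and averaging", {
  cm <- randomContactMatrix(80, seed = 21)
  grid <- genomeGrid(cm)
  bins <- c(10, 30, 55, 75)
  anchors <- pointAnchors("chrA", bins, grid)
  w <- 4L
  res <- peScan(cm, anchors, windowBp = w * 100, maxSepBp = 8000,
                minSepBp = 900, background = "none")
  # oracle: all pairs with separation in [9, 80] bins, averaged windows
  m <- cisMatrix(cm, "chrA")
  cmb <- combn(bins, 2)
  subs <- list()
  for (k in seq_len(ncol(cmb))) {
    sep <- cmb[2, k] - cmb[1, k]
    if (sep < 9 || sep > 80) next
    sub <- bruteWindow(m, cmb[1, k], cmb[2, k], w)
    if (!is.null(sub)) subs[[length(subs) + 1]] <- sub
  }
  expected <- Reduce(`+`, subs) / length(subs)
  expect_equal(nFeatures(res), length(subs))
  expect_equal(aggregateMatrix(res), expected, tolerance = 1e-12)
})

test_that("PE-SCAn is flat on uniform matrices and recovers point boosts", {
  grid <- toyGrid(c(chrA = 100L))
  mu <- matrix(2, 100, 100)
  cmu <- ContactMatrix(grid, list(chrA = mu), valueKind = "balanced")
  anchors <- pointAnchors("chrA", c(20, 50, 80), grid)
  resU <- peScan(cmu, anchors, windowBp = 300, maxSepBp = 1e4,
                 background = "permute", seed = 2)
  expect_true(all(abs(aggregateMatrix(resU) - 2) < 1e-12))
  expect_true(all(abs(aggregateStats(resU)$ratio - 1) < 1e-12))
  expect_equal(aggregateStats(resU)$centerEnrichment, 1)
  # anchors boosted to 3 on background 1: ratio center ~ 3, frame ~ 1
  m3 <- matrix(1, 100, 100)
  for (k in list(c(20, 50), c(20, 80), c(50, 80))) {
    m3[k[1], k[2]] <- 3; m3[k[2], k[1]] <- 3
  }
  cm3 <- ContactMatrix(grid, list(chrA = m3), valueKind = "balanced")
  res3 <- peScan(cm3, anchors, windowBp = 300, maxSepBp = 1e4,
                 background = "permute", seed = 2)
  rat <- aggregateStats(res3)$ratio
  ctr <- (nrow(rat) + 1) / 2
  expect_equal(rat[ctr, ctr], 3, tolerance = 0.01)
  frame <- c(rat[1, ], rat[nrow(rat), ], rat[, 1], rat[, ncol(rat)])
  expect_true(all(abs(frame - 1) < 0.05))
})

test_that("PE-SCAn permuted background is calibrated around one", {
  cm <- randomContactMatrix(120, seed = 33, binBp = 1000L)
  grid <- genomeGrid(cm)
  enr <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    anchors <- pointAnchors("chrA", sort(sample(5:115, 5)), grid)
    res <- peScan(cm, anchors, windowBp = 3000, maxSepBp = 1.2e5,
                  background = "permute", seed = s)
    if (nFeatures(res) == 0) return(NA_real_)
    aggregateStats(res)$centerEnrichment
  }, numeric(1))
  enr <- enr[!is.na(enr)]
  se <- sd(enr) / sqrt(length(enr))
  expect_lt(abs(mean(enr) - 1), max(2 * se, 0.02))
})

test_that("aggregate operators are linear in the matrix", {
  a <- randomContactMatrix(60, seed = 41)
  b <- randomContactMatrix(60, seed = 42)
  grid <- genomeGrid(a)
  s <- a
  s@cis$chrA <- a@cis$chrA + b@cis$chrA
  anchors <- pointAnchors("chrA", c(10, 30, 50), grid)
  pa <- peScan(a, anchors, windowBp = 300, maxSepBp = 6000,
               background = "none")
  pb <- peScan(b, anchors, windowBp = 300, maxSepBp = 6000,
               background = "none")
  ps <- peScan(s, anchors, windowBp = 300, maxSepBp = 6000,
               background = "none")
  expect_equal(aggregateMatrix(ps),
               aggregateMatrix(pa) + aggregateMatrix(pb),
               tolerance = 1e-12)
})

test_that("loop APA summarizes center against the bottom-left corner", {
  grid <- toyGrid(c(chrA = 40L))
  # uniform O/E: summary exactly 1
  oeu <- ContactMatrix(grid, list(chrA = matrix(1, 40, 40)),
                       valueKind = "oe")
  loops <- LoopSet(pointAnchors("chrA", c(10, 25), grid)[1],
                   pointAnchors("chrA", c(10, 25), grid)[2])
  resU <- loopApa(oeu, loops, halfWindowBins = 3L)
  expect_equal(aggregateStats(resU)$cornerRatio, 1)
  # constructed window: center 2.4, bottom-left 3x3 corner 1.2 -> 2.0
  m <- matrix(1, 40, 40)
  m[10, 25] <- 2.4; m[25, 10] <- 2.4
  m[11:13, 22:24] <- 1.2                 # rows below center, cols left
  m[22:24, 11:13] <- 1.2
  oe2 <- ContactMatrix(grid, list(chrA = m), valueKind = "oe")
  res2 <- loopApa(oe2, loops, halfWindowBins = 3L, cornerSize = 3L)
  expect_equal(aggregateStats(res2)$cornerRatio, 2.0)
  expect_equal(perFeatureValues(res2)[1], mean(m[9:11, 24:26]))
  # loops too close to the diagonal are skipped and counted
  close <- LoopSet(pointAnchors("chrA", c(10, 14), grid)[1],
                   pointAnchors("chrA", c(10, 14), grid)[2])
  res3 <- loopApa(oeu, close, halfWindowBins = 3L)
  expect_equal(nFeatures(res3), 0L)
  expect_equal(aggregateStats(res3)$skippedClose, 1L)
})

test_that("loop APA recovers the generator's focal boost", {
  cfg <- simulationConfig(chromLengths = c(chrS1 = 1e7, chrS2 = 1e7),
                          depth = 8e6, lambda = 2.5,
                          hotspotsPerChrom = 4L,
                          loopsPerClass = c(ctcf_cohesin = 8L,
                                            pol2_only = 0L, both = 0L),
                          stripesPerChrom = 0L, promotersPerChrom = 8L)
  exp <- makeExperiment(cfg)
  oe <- observedOverExpected(iceBalance(exp$untreated))
  res <- loopApa(oe, exp$truth@loops, halfWindowBins = 5L)
  # center/corner ratio within 10% of the injected boost at high depth;
  # the domain background under the loop inflates both corner and center
  expect_gt(nFeatures(res), 4L)
  expect_lt(abs(aggregateStats(res)$cornerRatio - cfg$lambda),
            0.1 * cfg$lambda)
})

test_that("promoter-pair strata follow distance, tertile and CTCF rules", {
  grid <- toyGrid(c(chrA = 400L), binBp = 10000L)
  # uniform matrix: every stratum's center enrichment is 1
  oeu <- ContactMatrix(grid, list(chrA = matrix(1, 400, 400)),
                       valueKind = "oe")
  set.seed(2)
  bins <- sort(sample(30:370, 12))
  prom <- pointAnchors("chrA", bins, grid)
  mcols(prom)$activity <- rev(seq_along(bins))  # distinct scores
  res <- promoterPairAggregate(oeu, prom, windowBp = 2e5)
  expect_true(length(res) > 0)
  for (r in res) {
    expect_equal(aggregateStats(r)$centerEnrichment, 1, tolerance = 1e-12)
  }
  # tertile sizes: 12 -> 4/4/4; 10 -> 4/3/3 (remainder to higher slices)
  expect_equal(as.integer(table(HiCdegron:::.tertiles(1:12))), c(4L, 4L, 4L))
  t10 <- HiCdegron:::.tertiles(1:10)
  expect_equal(as.integer(table(t10)), c(4L, 3L, 3L))
  expect_equal(as.integer(table(HiCdegron:::.tertiles(1:9))), c(3L, 3L, 3L))
  # the top tertile holds the highest scores
  expect_true(all(t10[order(1:10, decreasing = TRUE)[1:4]] == "high"))
  # a boost confined to active+CTCF pairs shows up in that stratum only
  cfg <- simulationConfig(chromLengths = c(chrS1 = 2e7), depth = 4e6,
                          promoterPairBoost = 2.5,
                          hotspotsPerChrom = 4L, stripesPerChrom = 0L,
                          promotersPerChrom = 30L)
  exp <- makeExperiment(cfg)
  oe <- observedOverExpected(iceBalance(exp$untreated))
  pr <- exp$truth@promoters
  ctcfPeaks <- GRanges(seqnames(pr)[mcols(pr)$ctcfBound],
                       IRanges(start = start(pr)[mcols(pr)$ctcfBound],
                               end = end(pr)[mcols(pr)$ctcfBound]))
  mcols(pr) <- mcols(pr)["activity"]
  strata <- promoterPairAggregate(oe, pr, windowBp = 2e5,
                                  ctcfPeaks = ctcfPeaks)
  hiC <- strata[["intra_tad.high.ctcf"]]
  others <- strata[setdiff(names(strata), "intra_tad.high.ctcf")]
  others <- others[!vapply(others, is.null, logical(1))]
  expect_false(is.null(hiC))
  ce <- vapply(others, function(r) aggregateStats(r)$centerMean, numeric(1))
  expect_gt(aggregateStats(hiC)$centerMean, max(ce))
})

test_that("stripe profiles recover boosted bands and their extent", {
  grid <- toyGrid(c(chrA = 100L), binBp = 10000L)
  # uniform matrix: curve = 1 everywhere
  oeu <- ContactMatrix(grid, list(chrA = matrix(1, 100, 100)),
                       valueKind = "oe")
  targets <- pointAnchors("chrA", c(40, 70), grid)
  sp <- stripeProfile(oeu, targets, maxDistBp = 2e5)
  expect_equal(sp$curve$value, rep(1, 20))
  # boost 2 with extent 100 kb, probed to 200 kb: ~2 then ~1
  m <- matrix(1, 100, 100)
  for (t0 in c(40, 70)) {
    j <- (t0 - 10):(t0 + 10)
    m[t0, j] <- 2; m[j, t0] <- 2
  }
  oe2 <- ContactMatrix(grid, list(chrA = m), valueKind = "oe")
  sp2 <- stripeProfile(oe2, targets, maxDistBp = 2e5)
  expect_true(all(sp2$curve$value[1:10] == 2))
  expect_true(all(sp2$curve$value[11:20] == 1))
  # truncation near the chromosome end is flagged
  edge <- pointAnchors("chrA", 3, grid)
  spE <- stripeProfile(oeu, edge, maxDistBp = 2e5)
  expect_equal(aggregateStats(spE$result)$truncated, 1L)
  # generator stripe of boost 1.5 with extent 200 kb on the noiseless map
  cfg <- simulationConfig(chromLengths = c(chrS1 = 1e7), sigma = 1.5,
                          stripesPerChrom = 3L, hotspotsPerChrom = 4L,
                          loopsPerClass = c(ctcf_cohesin = 2L,
                                            pol2_only = 2L, both = 0L),
                          promotersPerChrom = 8L)
  truth <- synthesizeTruth(cfg)
  oeT <- observedOverExpected(intensityAsMatrix(truth))
  spT <- stripeProfile(oeT, truth@stripes, maxDistBp = 2e5)
  # stripe pixels carry ~sigma relative enrichment across the extent
  expect_true(all(spT$curve$value > 1.3 & spT$curve$value < 1.7))
})
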