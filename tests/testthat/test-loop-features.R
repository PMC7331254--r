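mkLoop <- function(b1, b2, grid, chrom = "chrA") {
  bs <- binSize(grid)
  a1 <- GRanges(chrom, IRanges(start = (b1 - 1) * bs + 40,
                               end = (b1 - 1) * bs + 60))
  a2 <- GRanges(chrom, IRanges(start = (b2 - 1) * bs + 40,
                               end = (b2 - 1) * bs + 60))
  LoopSet(a1, a2)
}

test_that("occupancy classification follows the both/single/none rule", {
  grid <- toyGrid(c(chrA = 50L))
  loops <- LoopSet(
    GRanges("chrA", IRanges(start = c(100, 600, 1100, 1600, 2100, 2600),
                            width = 50)),
    GRanges("chrA", IRanges(start = c(3100, 3600, 4100, 4600, 4800, 4900),
                            width = 50)))
  # factor 1 peaks: overlap anchors so loops score both:2, single:3, none:1
  f1 <- GRanges("chrA", IRanges(start = c(110, 3110,   # loop 1 both
                                          610, 3610,   # loop 2 both
                                          1110,        # loop 3 single
                                          4610,        # loop 4 single
                                          2110),       # loop 5 single
                                width = 20))
  f2 <- GRanges("chrA", IRanges(start = c(110, 610), width = 20))
  calls <- classifyLoops(loops, list(one = f1, two = f2))
  expect_equal(as.integer(table(calls$factor_one)), c(2L, 3L, 1L))
  expect_equal(as.character(calls$factor_one),
               c("both", "both", "single", "single", "single", "none"))
  # empty peak set: every loop is none for that factor
  calls2 <- classifyLoops(loops, list(x = GRanges()))
  expect_true(all(calls2$factor_x == "none"))
  # compound predicate selection
  pol2 <- f1; coh <- GRanges(); ct <- GRanges()
  c3 <- classifyLoops(loops, list(pol2 = pol2, cohesin = coh, ctcf = ct))
  sel <- selectLoopClass(c3, pol2 = "both", cohesin = "none", ctcf = "none")
  expect_equal(which(sel), c(1L, 2L))
})

test_that("classification is monotone in anchor padding", {
  grid <- toyGrid(c(chrA = 50L))
  set.seed(9)
  loops <- LoopSet(
    GRanges("chrA", IRanges(start = sort(sample(1:2000, 8)), width = 30)),
    GRanges("chrA", IRanges(start = sort(sample(2500, 8) + 2500), width = 30)))
  peaks <- GRanges("chrA", IRanges(start = sample(1:4900, 15), width = 40))
  rank_ <- c(both = 2L, single = 1L, none = 0L)
  prev <- NULL
  for (slop in c(0, 50, 200, 1000)) {
    calls <- classifyLoops(loops, list(p = peaks), slopBp = slop)
    cur <- rank_[as.character(calls$factor_p)]
    if (!is.null(prev)) expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("loop strength reads center pixels and 3x3 means", {
  grid <- toyGrid(c(chrA = 30L))
  m <- matrix(1, 30, 30)
  m[10, 20] <- 2.7; m[20, 10] <- 2.7
  m[14:16, 24:26] <- 1; m[15, 25] <- 10
  m[24:26, 14:16] <- t(m[14:16, 24:26])
  cm <- ContactMatrix(grid, list(chrA = m), valueKind = "oe")
  loops <- c1 <- mkLoop(10, 20, grid)
  expect_equal(loopStrength(cm, loops, "center_pixel"), 2.7)
  l2 <- mkLoop(15, 25, grid)
  expect_equal(loopStrength(cm, l2, "center_3x3_mean"), 2.0)
  # masked center gives NA
  m[10, 20] <- NA; m[20, 10] <- NA
  cmNA <- ContactMatrix(grid, list(chrA = m), valueKind = "oe")
  expect_true(is.na(loopStrength(cmNA, c1, "center_pixel")))
})

test_that("percent change matches the printed definition exactly", {
  cs <- percentChange(rep(10, 5), rep(8.74, 5))
  expect_equal(cs$percentChange, -12.6, tolerance = 1e-12)
  expect_equal(percentChange(1:10, 1:10)$percentChange, 0)
  expect_error(percentChange(c(0, 0), c(1, 2)), "untreated mean")
  # scale invariance
  set.seed(1)
  u <- runif(30, 1, 2); t_ <- runif(30, 1, 2)
  a <- percentChange(u, t_)
  b <- percentChange(u * 37.5, t_ * 37.5)
  expect_equal(a$percentChange, b$percentChange, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  # paired mode drops incomplete pairs and tightens the s.e.
  t2 <- u * 0.9 + rnorm(30, 0, 0.01)
  pc <- percentChange(u, t2, paired = TRUE)
  up <- percentChange(u, t2, paired = FALSE)
  expect_lt(pc$se, up$se)
  expect_lt(pc$pValue, 0.01)
})

test_that("loop-length trend fits flat and linear relations", {
  grid <- toyGrid(c(chrA = 2000L), binBp = 1000L)
  set.seed(4)
  b1 <- sort(sample(10:900, 60))
  b2 <- b1 + sample(30:900, 60, TRUE)
  bs <- binSize(grid)
  loops <- LoopSet(GRanges("chrA", IRanges((b1 - 1) * bs + 1, width = 100)),
                   GRanges("chrA", IRanges((b2 - 1) * bs + 1, width = 100)))
  # constant values: flat curve
  tr <- loopLengthTrend(loops, rep(3.3, 60), span = 0.5)
  expect_true(all(abs(tr$curve$fitted - 3.3) < 1e-6))
  # identity relation recovered within 1% on interior grid points
  len <- loopLengths(loops)
  tr2 <- loopLengthTrend(loops, as.numeric(len), span = 0.5)
  interior <- tr2$curve$length > quantile(len, 0.1) &
    tr2$curve$length < quantile(len, 0.9)
  relErr <- abs(tr2$curve$fitted - tr2$curve$length) / tr2$curve$length
  expect_true(all(relErr[interior] < 0.01))
  # two-group summary splits at the threshold
  expect_equal(sum(tr2$twoGroup$n), 60L)
  expect_equal(tr2$twoGroup$group, c("small", "large"))
  # < 10 loops: binned means only, with a warning
  expect_warning(tr3 <- loopLengthTrend(loops[1:5], rep(1, 5)), "10 loops")
  expect_null(tr3$curve)
})

test_that("domains rank by transcription with stable ties and remainders", {
  grid <- toyGrid(c(chrA = 100L), binBp = 1000L)
  doms <- GRanges("chrA", IRanges(start = c(1, 20001, 40001, 60001, 80001),
                                  width = 10000))
  v <- rep(0, 100)
  v[1:10] <- 5; v[21:30] <- 1; v[41:50] <- 3; v[61:70] <- 3; v[81:90] <- 0.5
  tr <- BinnedTrack(grid, v)
  rk <- rankDomainsByTranscription(doms, tr, flankBp = 0, nGroups = 2L)
  # scores 5, 1, 3, 3, 0.5 -> top group: domain 1 and the leftmost tie
  expect_equal(as.integer(rk$group), c(1L, 2L, 1L, 1L, 2L))
  expect_equal(rk$score, c(5, 1, 3, 3, 0.5))
  # remainder rule: 5 domains in 2 groups -> sizes 3/2
  expect_equal(as.integer(table(rk$group)), c(3L, 2L))
  # all-equal scores: stable rank by coordinate
  rk2 <- rankDomainsByTranscription(doms, BinnedTrack(grid, 1), 0, 2L)
  expect_equal(as.integer(rk2$group), c(1L, 1L, 1L, 2L, 2L))
})

test_that("hotspot stitching merges by gap and cuts at the tangent point", {
  grid <- toyGrid(c(chrA = 100L), binBp = 10000L)
  # two peaks 10 kb apart merge; 20 kb apart stay separate
  p1 <- GRanges("chrA", IRanges(start = c(1, 12001), width = 2000),
                signal = c(1, 1))
  expect_equal(length(stitchHotspots(p1, 12500)$clusters), 1L)
  p2 <- GRanges("chrA", IRanges(start = c(1, 22001), width = 2000),
                signal = c(1, 1))
  expect_equal(length(stitchHotspots(p2, 12500)$clusters), 2L)
  # 20 well-separated clusters with signals 1..19 and 1000: only the
  # outlier passes the tangent cutoff
  sig <- c(1:19, 1000)
  p3 <- GRanges("chrA", IRanges(start = (0:19) * 40000 + 1, width = 1000),
                signal = sig)
  res <- stitchHotspots(p3, 12500)
  expect_equal(length(res$hotspots), 1L)
  expect_equal(mcols(res$hotspots)$signal, 1000)
  expect_equal(res$cutoffSignal, bruteTangentCutoff(sig))
  # summit is the strongest constituent peak's midpoint
  p4 <- GRanges("chrA", IRanges(start = c(1, 5001, 9001), width = 1000),
                signal = c(2, 9, 3))
  res4 <- stitchHotspots(p4, 12500)
  expect_equal(mcols(res4$clusters)$summit, 5500)
  # invariance to input order
  set.seed(6)
  perm <- sample(length(p3))
  resP <- stitchHotspots(p3[perm], 12500)
  expect_equal(start(resP$clusters), start(res$clusters))
  expect_equal(mcols(resP$clusters)$signal, mcols(res$clusters)$signal)
  expect_equal(resP$cutoffSignal, res$cutoffSignal)
})

test_that("change-signal correlations behave at the extremes and the null", {
  set.seed(8)
  d <- rnorm(50)
  res <- changeVsSignalCorrelation(d, list(same = d, neg = -d))
  expect_equal(res$pearson, c(1, -1))
  expect_equal(res$spearman, c(1, -1))
  # independent vectors: mean |r| small over repeated draws
  rs <- vapply(1:100, function(s) {
    set.seed(s)
    changeVsSignalCorrelation(rnorm(200), list(x = rnorm(200)))$pearson
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.1)
  # fewer than 3 complete pairs: NA coefficient
  res2 <- changeVsSignalCorrelation(c(1, 2, NA), list(x = c(1, NA, 3)))
  expect_true(is.na(res2$pearson))
  expect_equal(res2$n, 1L)
})
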