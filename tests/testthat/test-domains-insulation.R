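test_that("insulation is zero on uniform matrices and dips at boundaries", {
  grid <- toyGrid(c(chrA = 12L))
  mu <- matrix(3, 12, 12)
  cm <- ContactMatrix(grid, list(chrA = mu), valueKind = "balanced")
  ins <- insulationScore(cm, 2 * binSize(grid))
  v <- trackValues(ins)
  expect_true(all(abs(v[3:10]) < 1e-12))
  expect_true(all(is.na(v[c(1, 2, 11, 12)])))
  # two adjacent blocks separated at bin 4 of an 8-bin chromosome
  m <- matrix(0.2, 8, 8)
  m[1:4, 1:4] <- 2
  m[5:8, 5:8] <- 2
  grid8 <- toyGrid(c(chrA = 8L))
  cm8 <- ContactMatrix(grid8, list(chrA = m), valueKind = "balanced")
  ins8 <- insulationScore(cm8, 2 * binSize(grid8))
  v8 <- trackValues(ins8)
  expect_equal(which.min(v8), 4L)
  # brute-force equality on the same matrix
  expect_equal(v8, bruteInsulation(m, 2))
  # window too large for the chromosome
  grid5 <- toyGrid(c(chrA = 5L))
  cm5 <- ContactMatrix(grid5, list(chrA = matrix(1, 5, 5)),
                       valueKind = "balanced")
  expect_error(insulationScore(cm5, 3 * binSize(grid5)), "too large")
})

test_that("insulation equals the brute-force diamond on random matrices", {
  for (s in 1:3) {
    n <- sample(20:50, 1)
    cm <- randomContactMatrix(n, seed = s)
    w <- sample(2:5, 1)
    ins <- insulationScore(cm, w * 100L)
    expect_equal(trackValues(ins),
                 bruteInsulation(cisMatrix(cm, "chrA"), w),
                 tolerance = 1e-12, info = sprintf("seed %d", s))
  }
})

test_that("boundary calling respects prominence and tie-breaks", {
  grid <- toyGrid(c(chrA = 11L))
  # monotone track: no boundaries
  tr <- BinnedTrack(grid, seq(0, 1, length.out = 11))
  expect_equal(length(boundariesFromInsulation(tr, 3L, 0.1)), 0L)
  # a single minimum of prominence 0.6 at bin 6
  v <- c(0.5, 0.6, 0.7, 0.6, 0.4, 0.0, 0.4, 0.5, 0.5, 0.6, 0.5)
  # flanking maxima within 3 bins: 0.7 (left) and 0.5 (right) -> mean
  # minus the minimum = 0.6
  tr2 <- BinnedTrack(grid, v)
  b <- boundariesFromInsulation(tr2, 3L, 0.5)
  expect_equal(length(b), 1L)
  expect_equal(start(b), 501)    # bin 6
  expect_equal(mcols(b)$prominence, 0.6)
  expect_equal(length(boundariesFromInsulation(tr2, 3L, 0.7)), 0L)
  # two equal adjacent minima: the leftmost is reported
  v3 <- c(1, 1, 0.1, 0.1, 1, 1, 1, 1, 1, 1, 1)
  b3 <- boundariesFromInsulation(BinnedTrack(grid, v3), 2L, 0.5)
  expect_equal(length(b3), 1L)
  expect_equal(start(b3), 201)   # bin 3
})

test_that("average profiles around features", {
  grid <- toyGrid(c(chrA = 20L))
  tr <- BinnedTrack(grid, 1.5)
  feats <- GRanges("chrA", IRanges(start = c(501, 1001), width = 100))
  prof <- averageProfileAt(tr, feats, 300)
  expect_equal(prof$value, rep(1.5, 7))
  # a single feature returns the track slice
  v <- seq_len(20) / 10
  tr2 <- BinnedTrack(grid, v)
  prof2 <- averageProfileAt(tr2, feats[1], 200)
  expect_equal(prof2$value, v[4:8])
  # two features with slices (0,1,0) and (0,3,0) average to (0,2,0)
  v3 <- rep(0, 20); v3[6] <- 1; v3[11] <- 3
  prof3 <- averageProfileAt(BinnedTrack(grid, v3),
                            GRanges("chrA", IRanges(start = c(501, 1001),
                                                    width = 100)), 100)
  expect_equal(prof3$value, c(0, 2, 0))
})

test_that("area-weighted rescaling preserves means and matches the oracle", {
  m <- matrix(1:16, 4, 4)
  m <- m + t(m)
  expect_identical(rescaleSubmatrix(m, 4L), m)
  # 2x2 -> 4x4 replicates each value in its quadrant
  m2 <- matrix(c(1, 2, 2, 5), 2, 2)
  up <- rescaleSubmatrix(m2, 4L)
  expect_equal(up, m2[rep(1:2, each = 2), rep(1:2, each = 2)])
  # 3x3 of ones -> 2x2 of ones under fractional overlap
  expect_equal(rescaleSubmatrix(matrix(1, 3, 3), 2L), matrix(1, 2, 2))
  # exact mean preservation and oracle equality on random inputs
  for (s in 1:4) {
    set.seed(s)
    n <- sample(3:15, 1)
    out <- sample(2:12, 1)
    x <- matrix(runif(n * n), n, n)
    r <- rescaleSubmatrix(x, out)
    expect_equal(mean(r), mean(x), tolerance = 1e-12)
    expect_equal(r, bruteRescale(x, out), tolerance = 1e-10)
  }
})

test_that("meta-domain pile-up rescales and averages the central third", {
  # a single domain on a uniform O/E of 1 gives a matrix of ones
  grid <- toyGrid(c(chrA = 60L))
  oe1 <- ContactMatrix(grid, list(chrA = matrix(1, 60, 60)),
                       valueKind = "oe")
  dom <- GRanges("chrA", IRanges(start = 2001, end = 3000))  # bins 21-30
  r1 <- metaDomainPileup(oe1, dom, outSize = 30L)
  expect_equal(nFeatures(r1), 1L)
  expect_true(all(abs(aggregateMatrix(r1) - 1) < 1e-9))
  # two domains with central blocks 1.2 and 1.8 on background 1
  m <- matrix(1, 60, 60)
  m[21:30, 21:30] <- 1.2
  m[41:50, 41:50] <- 1.8
  oe2 <- ContactMatrix(grid, list(chrA = m), valueKind = "oe")
  doms <- GRanges("chrA", IRanges(start = c(2001, 4001), end = c(3000, 5000)))
  r2 <- metaDomainPileup(oe2, doms, outSize = 30L)
  expect_equal(aggregateStats(r2)$centralThirdMean, 1.5, tolerance = 1e-9)
  expect_equal(perFeatureValues(r2), c(1.2, 1.8), tolerance = 1e-9)
  # averaging k identical domains equals the single-domain result
  r3 <- metaDomainPileup(oe2, c(doms[1], doms[1], doms[1]), outSize = 30L)
  r4 <- metaDomainPileup(oe2, doms[1], outSize = 30L)
  expect_equal(aggregateMatrix(r3), aggregateMatrix(r4), tolerance = 1e-12)
  # domains too short or with windows off the chromosome are skipped
  shortDom <- GRanges("chrA", IRanges(start = 1, end = 200))
  expect_warning(r5 <- metaDomainPileup(oe1, shortDom), "skipped")
  expect_equal(nFeatures(r5), 0L)
  # empty set: empty result, no error
  r6 <- metaDomainPileup(oe1, GRanges())
  expect_equal(nFeatures(r6), 0L)
})

test_that("intra-domain enrichment averages inside-domain cells", {
  grid <- toyGrid(c(chrA = 20L))
  m <- matrix(1, 20, 20)
  m[6:10, 6:10] <- 1.5
  oe <- ContactMatrix(grid, list(chrA = m), valueKind = "oe")
  dom <- GRanges("chrA", IRanges(start = 501, end = 1000))
  expect_equal(intraDomainEnrichment(oe, dom, minDistBins = 1L), 1.5)
  # fully masked domain gives NA
  m2 <- m
  m2[6:10, 6:10] <- NA
  oe2 <- ContactMatrix(grid, list(chrA = m2), valueKind = "oe")
  expect_true(is.na(intraDomainEnrichment(oe2, dom, minDistBins = 1L)))
  # distance filter excludes the near-diagonal
  m3 <- matrix(1, 20, 20)
  m3[cbind(6:9, 7:10)] <- 100
  m3[cbind(7:10, 6:9)] <- 100
  oe3 <- ContactMatrix(grid, list(chrA = m3), valueKind = "oe")
  expect_equal(intraDomainEnrichment(oe3, dom, minDistBins = 2L), 1)
})
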