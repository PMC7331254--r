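test_that("pair filtering removes duplicates and same-fragment pairs", {
  frags <- GRanges("chrA", IRanges(start = seq(1, 901, by = 100), width = 100))
  pairs <- data.frame(
    chrom1 = "chrA", pos1 = c(10, 10, 110, 310, 520),
    strand1 = c("+", "+", "+", "-", "+"),
    chrom2 = "chrA", pos2 = c(250, 250, 450, 650, 580),
    strand2 = c("-", "-", "+", "-", "+"))
  # row 2 duplicates row 1; row 5 has both ends on fragment 6
  res <- filterPairs(pairs, fragments = frags)
  expect_equal(nrow(res$pairs), 3L)
  expect_equal(unname(res$stats[c("duplicate", "same_fragment")]), c(1L, 1L))
  # clean input passes unchanged
  clean <- pairs[c(1, 3, 4), ]
  res2 <- filterPairs(clean, fragments = frags)
  expect_equal(nrow(res2$pairs), 3L)
  expect_equal(unname(res2$stats[["retained"]]), 3L)
  # empty input
  res3 <- filterPairs(pairs[0, ], fragments = frags)
  expect_equal(nrow(res3$pairs), 0L)
  expect_equal(unname(res3$stats[["retained"]]), 0L)
  # fragments required when ids absent
  expect_error(filterPairs(pairs), "fragment")
})

test_that("binning pairs conserves totals and fills cells symmetrically", {
  grid <- GenomeGrid(c(chrA = 1000), 100)
  p <- data.frame(chrom1 = "chrA", pos1 = c(10, 20, 410),
                  strand1 = "+",
                  chrom2 = "chrA", pos2 = c(150, 160, 480),
                  strand2 = "-")
  cm <- binPairs(p, grid)
  m <- cisMatrix(cm, "chrA")
  expect_equal(m[1, 2], 2)        # two pairs in bins (1, 2)
  expect_equal(m[2, 1], 2)        # symmetric query
  expect_equal(m[5, 5], 1)        # both ends in bin 5 -> diagonal
  expect_equal(totalContacts(cm), 3)
  # conservation for scattered pairs
  set.seed(7)
  p2 <- data.frame(chrom1 = "chrA", pos1 = sample(0:999, 10, TRUE),
                   strand1 = "+", chrom2 = "chrA",
                   pos2 = sample(0:999, 10, TRUE), strand2 = "-")
  cm2 <- binPairs(canonicalizePairs(p2), grid)
  m2 <- cisMatrix(cm2, "chrA")
  expect_equal(sum(m2[upper.tri(m2, diag = TRUE)]), 10)
  expect_equal(totalContacts(cm2), 10)
})

test_that("downsampling conserves totals exactly and is unbiased", {
  grid <- toyGrid(c(chrA = 4L))
  m <- matrix(0, 4, 4)
  m[1, 2] <- 100; m[2, 1] <- 100
  m[1, 3] <- 300; m[3, 1] <- 300
  m[2, 4] <- 600; m[4, 2] <- 600
  cm <- ContactMatrix(grid, list(chrA = m))
  expect_equal(totalContacts(cm), 1000)
  # identity and zero targets
  expect_equal(cisMatrix(downsampleContacts(cm, 1000), "chrA"), m)
  expect_equal(sum(cisMatrix(downsampleContacts(cm, 0, seed = 3), "chrA")), 0)
  expect_error(downsampleContacts(cm, 1001), "targetTotal")
  # exact conservation and reproducibility
  d1 <- downsampleContacts(cm, 500, seed = 11)
  d2 <- downsampleContacts(cm, 500, seed = 11)
  expect_equal(totalContacts(d1), 500)
  expect_equal(sum(cisMatrix(d1, "chrA")[upper.tri(m, diag = TRUE)]), 500)
  expect_identical(cisMatrix(d1, "chrA"), cisMatrix(d2, "chrA"))
  # Monte-Carlo mean of the 100-count cell over 200 seeds: 50 +/- 2
  draws <- vapply(seq_len(200), function(s)
    cisMatrix(downsampleContacts(cm, 500, seed = s), "chrA")[1, 2],
    numeric(1))
  expect_lt(abs(mean(draws) - 50), 2)
})

test_that("ICE balancing equalizes marginals and masks empty bins", {
  # uniform off-diagonal matrix: all weights equal, matrix stays uniform
  n <- 6
  m <- matrix(4, n, n); diag(m) <- 0
  grid <- toyGrid(c(chrA = as.integer(n)))
  cm <- ContactMatrix(grid, list(chrA = m))
  bal <- iceBalance(cm)
  w <- binWeights(bal, "chrA")
  expect_equal(w, rep(w[1], n))
  b <- cisMatrix(bal, "chrA")
  off <- b[upper.tri(b)]
  expect_equal(off, rep(off[1], length(off)))
  # a bin twice as visible: marginals equalize at convergence
  m2 <- matrix(rpois(n * n, 20), n, n)
  m2 <- m2 + t(m2); diag(m2) <- 0
  m2[2, ] <- m2[2, ] * 2
  m2[, 2] <- m2[2, ]
  cm2 <- ContactMatrix(grid, list(chrA = m2))
  bal2 <- iceBalance(cm2, tol = 1e-8)
  b2 <- cisMatrix(bal2, "chrA")
  marg <- rowSums(b2, na.rm = TRUE)
  expect_lt(sd(marg) / mean(marg), 1e-6)
  expect_true(bal2@metadata$converged)
  # balanced(i,j) = count(i,j) * w_i * w_j
  w2 <- binWeights(bal2, "chrA")
  expect_equal(b2, m2 * outer(w2, w2), tolerance = 1e-10)
  # all-zero bin is masked with missing weight
  m3 <- m2; m3[3, ] <- 0; m3[, 3] <- 0
  bal3 <- iceBalance(ContactMatrix(grid, list(chrA = m3)))
  expect_true(is.na(binWeights(bal3, "chrA")[3]))
  expect_true(all(is.na(cisMatrix(bal3, "chrA")[3, ])))
})

test_that("balancing is invariant to per-bin scaling up to global scale", {
  n <- 8
  set.seed(5)
  m <- matrix(rpois(n * n, 30), n, n)
  m <- m + t(m); diag(m) <- 0
  grid <- toyGrid(c(chrA = as.integer(n)))
  b1 <- cisMatrix(iceBalance(ContactMatrix(grid, list(chrA = m)),
                             tol = 1e-10), "chrA")
  m2 <- m
  m2[4, ] <- m2[4, ] * 3
  m2[, 4] <- m2[4, ]
  m2[4, 4] <- m[4, 4] * 9
  b2 <- cisMatrix(iceBalance(ContactMatrix(grid, list(chrA = m2)),
                             tol = 1e-10), "chrA")
  ratio <- b2 / b1
  ratio <- ratio[is.finite(ratio) & !is.na(ratio) & b1 > 0]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-4)
})

test_that("expected-by-distance matches enumeration and handles gaps", {
  # per-distance constant matrix reproduces the constants exactly
  n <- 5
  vd <- c(9, 7, 5, 3, 1)
  m <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) m[i, j] <- vd[abs(i - j) + 1]
  grid <- toyGrid(c(chrA = as.integer(n)))
  cm <- ContactMatrix(grid, list(chrA = m), valueKind = "balanced")
  e <- expectedByDistance(cm)$chrA$e
  expect_equal(e, vd)
  # 4-bin chromosome with distance-1 values (2, 4, 6): e(1) = 4
  m2 <- matrix(0, 4, 4)
  m2[1, 2] <- 2; m2[2, 3] <- 4; m2[3, 4] <- 6
  m2 <- m2 + t(m2)
  cm2 <- ContactMatrix(toyGrid(c(chrA = 4L)), list(chrA = m2),
                       valueKind = "balanced")
  prof <- expectedByDistance(cm2)
  expect_equal(prof$chrA$e[2], 4)
  # masked distance is NA, not zero
  m3 <- matrix(NA_real_, 3, 3)
  m3[1, 2] <- 1; m3[2, 1] <- 1
  diag(m3) <- 0
  cm3 <- ContactMatrix(toyGrid(c(chrA = 3L)), list(chrA = m3),
                       valueKind = "balanced")
  e3 <- expectedByDistance(cm3)$chrA
  expect_true(is.na(e3$e[3]))
  expect_equal(e3$nPairs[3], 0L)
  # random-matrix agreement with the enumeration oracle
  cmR <- randomContactMatrix(20, seed = 9)
  expect_equal(expectedByDistance(cmR)$chrA$e,
               bruteExpected(cisMatrix(cmR, "chrA")), tolerance = 1e-12)
})

test_that("O/E normalizes per-distance means to one", {
  cm <- randomContactMatrix(30, seed = 2)
  oe <- observedOverExpected(cm)
  m <- cisMatrix(oe, "chrA")
  for (d in 0:29) {
    i <- seq_len(30 - d)
    v <- m[cbind(i, i + d)]
    expect_lt(abs(mean(v, na.rm = TRUE) - 1), 1e-9)
  }
  # cell = 6 at a distance with reference e = 2 gives 3.0
  m2 <- matrix(0, 3, 3)
  m2[1, 2] <- 6; m2[2, 3] <- 2
  m2 <- m2 + t(m2)
  cm2 <- ContactMatrix(toyGrid(c(chrA = 3L)), list(chrA = m2),
                       valueKind = "balanced")
  prof <- list(chrA = list(e = c(1, 2, 1), nPairs = c(3L, 2L, 1L)))
  oe2 <- observedOverExpected(cm2, prof)
  expect_equal(cisMatrix(oe2, "chrA")[1, 2], 3.0)
  # O/E of a uniform matrix is all ones off any undefined cells
  mu <- matrix(5, 4, 4)
  cmu <- ContactMatrix(toyGrid(c(chrA = 4L)), list(chrA = mu),
                       valueKind = "balanced")
  oeu <- observedOverExpected(cmu)
  expect_true(all(abs(cisMatrix(oeu, "chrA") - 1) < 1e-12))
  # grid mismatch in the profile errors
  expect_error(observedOverExpected(cm2, list(chrB = prof$chrA)), "profile")
})

test_that("triplet matrix files round-trip and validate", {
  cm <- randomContactMatrix(10, seed = 3, kind = "count", integer = TRUE)
  mf <- tempfile(); bf <- tempfile()
  writeContactMatrix(cm, mf, bf)
  cm2 <- readContactMatrix(mf, bf)
  expect_equal(cisMatrix(cm2, "chrA"), cisMatrix(cm, "chrA"))
  expect_equal(binSize(genomeGrid(cm2)), binSize(genomeGrid(cm)))
  # (j, i) triplets are canonicalized to (i, j)
  bf2 <- writeTempLines(c("chrA\t0\t100\t1", "chrA\t100\t200\t2",
                          "chrA\t200\t300\t3"))
  mf2 <- writeTempLines("3\t1\t7")
  cm3 <- readContactMatrix(mf2, bf2)
  expect_equal(cisMatrix(cm3, "chrA")[1, 3], 7)
  # bin id outside the declared bins errors
  mf3 <- writeTempLines("1\t9\t4")
  expect_error(readContactMatrix(mf3, bf2), "outside")
  # bin width mismatch with the supplied grid errors
  grid50 <- GenomeGrid(c(chrA = 300), 50)
  expect_error(readContactMatrix(mf2, bf2, grid50), "match")
})

test_that("4DN pairs reader parses headers and canonicalizes ends", {
  f <- writeTempLines(c("## pairs format v1.0",
                        "#columns: readID chr1 pos1 chr2 pos2 strand1 strand2",
                        "r1\tchrA\t501\tchrA\t101\t+\t-",
                        "r2\tchrA\t51\tchrB\t11\t+\t+"))
  grid <- GenomeGrid(c(chrA = 1000, chrB = 1000), 100)
  p <- readPairs(f, grid)
  expect_equal(nrow(p), 2L)
  # intra-chromosomal record swapped so pos1 <= pos2 (0-based internally)
  expect_equal(p$pos1[1], 100)
  expect_equal(p$pos2[1], 500)
  expect_equal(p$chrom2[2], "chrB")
  bad <- writeTempLines("r1\tchrZ\t10\tchrZ\t20\t+\t-")
  expect_error(readPairs(bad, grid), "absent")
})
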