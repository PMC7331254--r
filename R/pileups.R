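#' AggregateResult accessors
#'
#' @param x an [AggregateResult-class].
#' @name AggregateResult-accessors
NULL

#' @rdname AggregateResult-accessors
#' @export
setMethod("aggregateMatrix", "AggregateResult", function(x) x@matrix)

#' @rdname AggregateResult-accessors
#' @export
setMethod("backgroundMatrix", "AggregateResult", function(x) x@background)

#' @rdname AggregateResult-accessors
#' @export
setMethod("nFeatures", "AggregateResult", function(x) x@nFeatures)

#' @rdname AggregateResult-accessors
#' @export
setMethod("perFeatureValues", "AggregateResult", function(x) x@perFeature)

#' @rdname AggregateResult-accessors
#' @export
setMethod("aggregateStats", "AggregateResult", function(x) x@stats)

setMethod("show", "AggregateResult", function(object) {
  cat(sprintf("AggregateResult: %d x %d pile-up over %d feature(s)\n",
              nrow(object@matrix), ncol(object@matrix), object@nFeatures))
  st <- object@stats
  for (nm in intersect(c("centerEnrichment", "cornerRatio", "centerMean"),
                       names(st))) {
    cat(sprintf("  %s: %s\n", nm, format(st[[nm]])))
  }
})

#' Center enrichment of a pile-up matrix
#'
#' Center pixel (or center `centerSize` x `centerSize` block mean) divided
#' by the mean of the outermost one-pixel frame.
#'
#' @param m a square matrix.
#' @param centerSize odd block size for the center (default 1).
#' @return a single numeric value.
#' @export
centerEnrichment <- function(m, centerSize = 1L) {
  n <- nrow(m)
  c0 <- (n + 1) %/% 2
  h <- (centerSize - 1) %/% 2
  ctr <- mean(m[(c0 - h):(c0 + h), (c0 - h):(c0 + h)], na.rm = TRUE)
  ctr / .frameMean(m)
}

#' Area-weighted submatrix rescaling
#'
#' Resamples a square `n x n` matrix to `outSize x outSize`: output cell
#' `(p, q)` is the mean of input values over the rectangle
#' `[p*n/out, (p+1)*n/out) x [q*n/out, (q+1)*n/out)`, with fractional
#' overlaps weighted by area. With no missing values the global mean is
#' preserved exactly; `NA` cells are excluded with their weight.
#'
#' @param sub square input matrix.
#' @param outSize output side length (>= 1).
#' @return an `outSize x outSize` matrix.
#' @export
rescaleSubmatrix <- function(sub, outSize) {
  n <- nrow(sub)
  if (is.null(n) || n != ncol(sub)) .stopf("sub must be square")
  if (outSize < 1) .stopf("outSize must be >= 1")
  if (n == outSize) return(sub)
  W <- .overlapWeights(n, outSize)
  ok <- !is.na(sub)
  z <- sub
  z[!ok] <- 0
  num <- W %*% z %*% t(W)
  den <- W %*% (ok + 0) %*% t(W)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# out x n row-stochastic matrix of fractional overlaps between output
# intervals [ (p-1)*n/out, p*n/out ) and input cells [i-1, i)
.overlapWeights <- function(n, out) {
  W <- matrix(0, out, n)
  step <- n / out
  for (p in seq_len(out)) {
    lo <- (p - 1) * step
    hi <- p * step
    i1 <- floor(lo) + 1
    i2 <- min(n, ceiling(hi))
    for (i in i1:i2) {
      ov <- min(hi, i) - max(lo, i - 1)
      if (ov > 0) W[p, i] <- ov
    }
    W[p, ] <- W[p, ] / step
  }
  W
}

#' Meta-domain pile-up
#'
#' Extracts, for each domain, the O/E submatrix over a window extending
#' the domain by its own length on both sides (so the window is three
#' domain lengths, with the domain in the central third), rescales it to
#' `outSize x outSize`, and averages per pixel across domains (missing
#' cells excluded per pixel). Domains shorter than 3 bins, or whose window
#' leaves the chromosome, are skipped and counted.
#'
#' @param oe an O/E [ContactMatrix-class].
#' @param domains a [GenomicRanges::GRanges] of cis domains.
#' @param outSize output matrix side (default 90; the central third spans
#'   indices 31..60).
#' @return an [AggregateResult-class]; `stats$centralThirdMean` is the mean
#'   over the central-third block, `perFeature` the per-domain
#'   central-third means.
#' @export
metaDomainPileup <- function(oe, domains, outSize = 90L) {
  grid <- oe@grid
  if (length(domains) == 0L) {
    return(new("AggregateResult", matrix = matrix(numeric(0), 0, 0),
               nFeatures = 0L, stats = list(skipped = 0L)))
  }
  acc <- matrix(0, outSize, outSize)
  cnt <- matrix(0, outSize, outSize)
  third <- seq(floor(outSize / 3) + 1, floor(outSize / 3) * 2 +
                 (outSize %% 3 > 0))
  perDom <- numeric(0)
  used <- 0L; skipped <- 0L
  ch <- as.character(seqnames(domains))
  .checkChrom(grid, unique(ch))
  for (k in seq_along(domains)) {
    n <- nBins(grid, ch[k])
    b1 <- localBin(grid, ch[k], start(domains)[k] - 1)
    b2 <- localBin(grid, ch[k], end(domains)[k] - 1)
    len <- b2 - b1 + 1
    if (len < 3) { skipped <- skipped + 1L; next }
    ws <- b1 - len
    we <- b2 + len
    if (ws < 1 || we > n) { skipped <- skipped + 1L; next }
    sub <- oe@cis[[ch[k]]][ws:we, ws:we]
    rs <- rescaleSubmatrix(sub, outSize)
    ok <- !is.na(rs)
    acc[ok] <- acc[ok] + rs[ok]
    cnt <- cnt + ok
    perDom <- c(perDom, mean(rs[third, third], na.rm = TRUE))
    used <- used + 1L
  }
  if (skipped) .warnf("%d domain(s) skipped (too short or window off chromosome)",
                      skipped)
  if (used == 0L) {
    return(new("AggregateResult", matrix = matrix(numeric(0), 0, 0),
               nFeatures = 0L, stats = list(skipped = skipped)))
  }
  m <- acc / cnt
  m[cnt == 0] <- NA_real_
  new("AggregateResult", matrix = m, nFeatures = used,
      perFeature = perDom,
      stats = list(centralThirdMean = mean(m[third, third], na.rm = TRUE),
                   centralThird = range(third), skipped = skipped,
                   outSize = outSize))
}

#' Intra-domain contact enrichment
#'
#' Per domain, the mean O/E over cell pairs with both bins inside the
#' domain at bin distance `>= minDistBins`. Suitable for two-sample
#' location tests (Wilcoxon) between conditions. Domains whose cells are
#' all masked give `NA`.
#'
#' @param oe an O/E [ContactMatrix-class].
#' @param domains a [GenomicRanges::GRanges].
#' @param minDistBins minimum bin distance counted (default 2; excludes
#'   the ligation-inflated near-diagonal).
#' @return numeric vector, one value per domain.
#' @export
intraDomainEnrichment <- function(oe, domains, minDistBins = 2L) {
  grid <- oe@grid
  ch <- as.character(seqnames(domains))
  if (length(domains)) .checkChrom(grid, unique(ch))
  vapply(seq_along(domains), function(k) {
    n <- nBins(grid, ch[k])
    b1 <- localBin(grid, ch[k], start(domains)[k] - 1)
    b2 <- localBin(grid, ch[k], end(domains)[k] - 1)
    m <- oe@cis[[ch[k]]][b1:b2, b1:b2, drop = FALSE]
    d <- abs(outer(seq_len(nrow(m)), seq_len(nrow(m)), "-"))
    v <- m[d >= minDistBins]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}
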