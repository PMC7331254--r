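# window extraction helper: (2w+1)^2 submatrix centred at (bi, bj); NULL
# if the window leaves the chromosome
.extractWindow <- function(m, bi, bj, w) {
  n <- nrow(m)
  if (bi - w < 1 || bi + w > n || bj - w < 1 || bj + w > n) return(NULL)
  m[(bi - w):(bi + w), (bj - w):(bj + w)]
}

# accumulate a window into running per-pixel sums/counts
.pileAccumulate <- function(state, sub) {
  ok <- !is.na(sub)
  if (is.null(state)) {
    state <- list(acc = matrix(0, nrow(sub), ncol(sub)),
                  cnt = matrix(0, nrow(sub), ncol(sub)))
  }
  state$acc[ok] <- state$acc[ok] + sub[ok]
  state$cnt <- state$cnt + ok
  state
}

.pileFinish <- function(state) {
  m <- state$acc / state$cnt
  m[state$cnt == 0] <- NA_real_
  m
}

# center block mean of a window (odd block size)
.centerBlockMean <- function(sub, blockSize = 3L) {
  c0 <- (nrow(sub) + 1) %/% 2
  h <- (blockSize - 1) %/% 2
  mean(sub[(c0 - h):(c0 + h), (c0 - h):(c0 + h)], na.rm = TRUE)
}

# all cis anchor-pair pixel coordinates for point anchors
.anchorPairs <- function(grid, anchors, maxSepBins, minSepBins) {
  ch <- as.character(seqnames(anchors))
  .checkChrom(grid, unique(ch))
  mid0 <- pmin(.mid(anchors) - 1, chromLengths(grid)[ch] - 1)
  out <- list()
  for (c1 in unique(ch)) {
    b <- sort(localBin(grid, ch[ch == c1], mid0[ch == c1]))
    if (length(b) < 2) next
    cmb <- utils::combn(b, 2)
    sep <- cmb[2, ] - cmb[1, ]
    keep <- sep >= minSepBins & sep <= maxSepBins
    if (!any(keep)) next
    out[[c1]] <- data.frame(chrom = c1, bin1 = cmb[1, keep],
                            bin2 = cmb[2, keep])
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Paired-end spatial chromatin analysis (PE-SCAn)
#'
#' For every cis pair of point anchors (e.g. binding-hotspot summits)
#' separated by at most `maxSepBp` (and at least `minSepBp`, which
#' defaults to the window half-width so the extracted square stays off the
#' diagonal), the `(2 w + 1)` square submatrix centred on the pair pixel is
#' extracted and averaged into a meta-matrix (`w = windowBp / bin size`).
#' The background repeats the procedure with anchors displaced to
#' uniformly random bins of their chromosome (anchor counts preserved;
#' seed-controlled), and the result also reports the raw/background ratio
#' matrix and the center enrichment (center pixel over the mean of the
#' outermost frame).
#'
#' @param cm a [ContactMatrix-class] (counts at matched depth, or O/E).
#' @param anchors point features ([GenomicRanges::GRanges]); midpoints are
#'   used.
#' @param windowBp half-width of the window in bp (default 500 kb).
#' @param maxSepBp maximum anchor-pair separation (default 10 Mb).
#' @param minSepBp minimum separation (default `windowBp`).
#' @param background `"permute"` or `"none"`.
#' @param nPermutations background replicates to average (default 1).
#' @param seed seed for the permuted background.
#' @return an [AggregateResult-class]; `perFeature` holds per-pair center
#'   3x3 means of the raw pile-up; `stats` includes `centerEnrichment`
#'   (of the ratio matrix when a background is computed, else of the raw),
#'   `backgroundCenterEnrichment`, `ratio`, and skip counts.
#' @export
peScan <- function(cm, anchors, windowBp = 5e5, maxSepBp = 1e7,
                   minSepBp = windowBp, background = c("permute", "none"),
                   nPermutations = 1L, seed = 1L) {
  background <- match.arg(background)
  grid <- cm@grid
  bs <- binSize(grid)
  w <- as.integer(round(windowBp / bs))
  pairs <- .anchorPairs(grid, anchors, floor(maxSepBp / bs),
                        max(1L, as.integer(ceiling(minSepBp / bs))))
  emptyRes <- function() new("AggregateResult",
                             matrix = matrix(numeric(0), 0, 0),
                             nFeatures = 0L, stats = list(nPairs = 0L))
  if (is.null(pairs)) return(emptyRes())
  state <- NULL
  per <- numeric(0)
  skippedEdge <- 0L
  for (k in seq_len(nrow(pairs))) {
    sub <- .extractWindow(cm@cis[[pairs$chrom[k]]], pairs$bin1[k],
                          pairs$bin2[k], w)
    if (is.null(sub)) { skippedEdge <- skippedEdge + 1L; next }
    state <- .pileAccumulate(state, sub)
    per <- c(per, .centerBlockMean(sub, 3L))
  }
  if (is.null(state)) return(emptyRes())
  raw <- .pileFinish(state)
  nUsed <- length(per)
  bg <- NULL
  if (background == "permute") {
    set.seed(seed)
    bstate <- NULL
    chTab <- table(as.character(seqnames(anchors)))
    for (r in seq_len(nPermutations)) {
      permAnchors <- .concatGR(lapply(names(chTab), function(c1) {
        nb <- nBins(grid, c1)
        b <- .sampleSafe(seq_len(nb), chTab[[c1]])
        pos <- (b - 1) * bs + floor(bs / 2)
        GRanges(c1, IRanges(start = pos, end = pos + 1))
      }))
      pp <- .anchorPairs(grid, permAnchors, floor(maxSepBp / bs),
                         max(1L, as.integer(ceiling(minSepBp / bs))))
      if (is.null(pp)) next
      for (k in seq_len(nrow(pp))) {
        sub <- .extractWindow(cm@cis[[pp$chrom[k]]], pp$bin1[k],
                              pp$bin2[k], w)
        if (is.null(sub)) next
        bstate <- .pileAccumulate(bstate, sub)
      }
    }
    if (!is.null(bstate)) bg <- .pileFinish(bstate)
  }
  stats <- list(nPairs = nUsed, skippedEdge = skippedEdge,
                windowBp = windowBp, minSepBp = minSepBp,
                maxSepBp = maxSepBp,
                centerMean = .centerBlockMean(raw, 3L),
                rawCenterEnrichment = centerEnrichment(raw))
  if (!is.null(bg)) {
    ratio <- raw / bg
    stats$ratio <- ratio
    stats$centerEnrichment <- centerEnrichment(ratio)
    stats$backgroundCenterEnrichment <- centerEnrichment(bg)
  } else {
    stats$centerEnrichment <- centerEnrichment(raw)
  }
  new("AggregateResult", matrix = raw, nFeatures = as.integer(nUsed),
      background = bg, perFeature = per, stats = stats)
}

#' Aggregate peak analysis (APA) for loops
#'
#' Averages the `(2 halfWindowBins + 1)` square O/E submatrices centred on
#' each loop pixel. Loops whose anchor-bin separation is not larger than
#' `2 halfWindowBins` (window would touch the diagonal) are skipped and
#' counted. The summary statistic is the center pixel divided by the mean
#' of the bottom-left corner block (the corner closest to the diagonal,
#' i.e. short-distance background), with a configurable corner block size.
#'
#' @param oe an O/E (or count) [ContactMatrix-class].
#' @param loops a [LoopSet-class].
#' @param halfWindowBins window half-width in bins (default 5).
#' @param cornerSize corner block side (default 3).
#' @return an [AggregateResult-class]; `perFeature` holds per-loop
#'   center 3x3 means (for downstream change statistics);
#'   `stats$cornerRatio` is the center-pixel / bottom-left summary.
#' @export
loopApa <- function(oe, loops, halfWindowBins = 5L, cornerSize = 3L) {
  grid <- oe@grid
  if (length(loops) == 0L) {
    return(new("AggregateResult", matrix = matrix(numeric(0), 0, 0),
               nFeatures = 0L, stats = list(skippedClose = 0L)))
  }
  lb <- .loopBins(loops, grid)
  w <- as.integer(halfWindowBins)
  state <- NULL
  per <- rep(NA_real_, length(loops))
  skippedClose <- 0L; skippedEdge <- 0L
  for (k in seq_len(nrow(lb))) {
    if (lb$bin2[k] - lb$bin1[k] <= 2L * w) { skippedClose <- skippedClose + 1L; next }
    sub <- .extractWindow(oe@cis[[lb$chrom[k]]], lb$bin1[k], lb$bin2[k], w)
    if (is.null(sub)) { skippedEdge <- skippedEdge + 1L; next }
    state <- .pileAccumulate(state, sub)
    per[k] <- .centerBlockMean(sub, 3L)
  }
  if (is.null(state)) {
    return(new("AggregateResult", matrix = matrix(numeric(0), 0, 0),
               nFeatures = 0L,
               stats = list(skippedClose = skippedClose,
                            skippedEdge = skippedEdge)))
  }
  m <- .pileFinish(state)
  side <- 2L * w + 1L
  c0 <- w + 1L
  corner <- m[(side - cornerSize + 1L):side, 1:cornerSize, drop = FALSE]
  cornerRatio <- m[c0, c0] / mean(corner, na.rm = TRUE)
  new("AggregateResult", matrix = m,
      nFeatures = as.integer(sum(!is.na(per))),
      perFeature = per,
      stats = list(cornerRatio = cornerRatio,
                   centerValue = m[c0, c0],
                   cornerMean = mean(corner, na.rm = TRUE),
                   cornerSize = cornerSize,
                   skippedClose = skippedClose, skippedEdge = skippedEdge))
}

#' Stratified promoter-pair aggregates
#'
#' Forms all cis promoter pairs, assigns each pair to a stratum by
#' distance class (`intra_tad`: 200 kb to 2 Mb; `long_range`: 2 to 10 Mb),
#' by activity tertile (both promoters in the same tertile of the
#' activity-ranked list; tertile sizes follow the remainder rule, e.g.
#' 4/3/3 for n = 10) and, optionally, by CTCF status (both promoters
#' with or without a CTCF peak within `ctcfSlopBp` of their midpoint;
#' mixed pairs are dropped from CTCF strata). Each stratum gets a pile-up
#' of the window centred on the pair pixel.
#'
#' @param oe an O/E [ContactMatrix-class].
#' @param promoters a [GenomicRanges::GRanges] with an `activity` score
#'   column.
#' @param windowBp window half-width in bp (default 200 kb, i.e. a
#'   400-kb square window).
#' @param ctcfPeaks optional [GenomicRanges::GRanges] of CTCF peaks; when
#'   given, strata are split by CTCF status.
#' @param ctcfSlopBp CTCF lookup slop around the promoter midpoint
#'   (default 5 kb).
#' @param distanceClasses named list of `c(min, max)` bp ranges.
#' @return a named list of [AggregateResult-class], one per non-empty
#'   stratum, with names like `intra_tad.high` or
#'   `intra_tad.high.ctcf`.
#' @export
promoterPairAggregate <- function(oe, promoters, windowBp = 2e5,
                                  ctcfPeaks = NULL, ctcfSlopBp = 5e3,
                                  distanceClasses = list(
                                    intra_tad = c(2e5, 2e6),
                                    long_range = c(2e6, 1e7))) {
  grid <- oe@grid
  bs <- binSize(grid)
  w <- as.integer(round(windowBp / bs))
  if (length(promoters) < 2) return(list())
  tert <- .tertiles(mcols(promoters)$activity)
  ctcfStatus <- if (!is.null(ctcfPeaks)) {
    mid <- .mid(promoters)
    probe <- GRanges(seqnames(promoters),
                     IRanges(start = pmax(1, mid - ctcfSlopBp),
                             end = mid + ctcfSlopBp))
    countOverlaps(probe, ctcfPeaks) > 0
  } else NULL
  ch <- as.character(seqnames(promoters))
  .checkChrom(grid, unique(ch))
  bin <- localBin(grid, ch, pmin(.mid(promoters) - 1,
                                 chromLengths(grid)[ch] - 1))
  idx <- utils::combn(seq_along(promoters), 2)
  sameCh <- ch[idx[1, ]] == ch[idx[2, ]]
  sepBp <- abs(bin[idx[1, ]] - bin[idx[2, ]]) * bs
  out <- list()
  for (dc in names(distanceClasses)) {
    rng <- distanceClasses[[dc]]
    inClass <- sameCh & sepBp >= rng[1] & sepBp <= rng[2]
    for (tl in levels(tert)) {
      both <- inClass & tert[idx[1, ]] == tl & tert[idx[2, ]] == tl
      strata <- if (is.null(ctcfStatus)) {
        list(all = both)
      } else {
        list(ctcf = both & ctcfStatus[idx[1, ]] & ctcfStatus[idx[2, ]],
             no_ctcf = both & !ctcfStatus[idx[1, ]] & !ctcfStatus[idx[2, ]])
      }
      for (sn in names(strata)) {
        sel <- which(strata[[sn]])
        if (!length(sel)) next
        state <- NULL
        per <- numeric(0)
        for (k in sel) {
          p1 <- idx[1, k]; p2 <- idx[2, k]
          b1 <- min(bin[p1], bin[p2]); b2 <- max(bin[p1], bin[p2])
          sub <- .extractWindow(oe@cis[[ch[p1]]], b1, b2, w)
          if (is.null(sub)) next
          state <- .pileAccumulate(state, sub)
          per <- c(per, .centerBlockMean(sub, 3L))
        }
        if (is.null(state)) next
        m <- .pileFinish(state)
        nm <- if (sn == "all") paste(dc, tl, sep = ".") else
          paste(dc, tl, sn, sep = ".")
        out[[nm]] <- new("AggregateResult", matrix = m,
                         nFeatures = length(per), perFeature = per,
                         stats = list(centerEnrichment = centerEnrichment(m),
                                      centerMean = .centerBlockMean(m, 3L),
                                      distanceClass = dc, tertile = tl,
                                      ctcf = sn))
      }
    }
  }
  out
}

#' Stripe decay profile
#'
#' Target-centred pile-up plus a decay curve: for each distance
#' `d = 1 .. maxDistBp / bin size`, the mean value over the pixels
#' connecting each target bin to the bins at distance `d` on either side
#' (both directions averaged). Targets within `maxDistBp` of a chromosome
#' end contribute truncated curves and are flagged in the stats.
#'
#' @param cm an O/E [ContactMatrix-class] (distance-normalized, so a flat
#'   curve at 1 means no stripe).
#' @param targets point features ([GenomicRanges::GRanges]).
#' @param maxDistBp maximum distance from the target centre (default
#'   200 kb).
#' @return a list with `curve` (data.frame: distanceBp, value, n) and
#'   `result` (an [AggregateResult-class] of the target-centred window,
#'   whose `perFeature` holds the per-target mean band value).
#' @export
stripeProfile <- function(cm, targets, maxDistBp = 2e5) {
  grid <- cm@grid
  bs <- binSize(grid)
  D <- as.integer(floor(maxDistBp / bs))
  ch <- as.character(seqnames(targets))
  .checkChrom(grid, unique(ch))
  sums <- numeric(D); cnts <- integer(D)
  state <- NULL
  truncated <- 0L
  perTarget <- rep(NA_real_, length(targets))
  for (k in seq_along(targets)) {
    n <- nBins(grid, ch[k])
    t0 <- localBin(grid, ch[k], min(.mid(targets[k]) - 1,
                                    chromLengths(grid)[[ch[k]]] - 1))
    if (t0 - D < 1 || t0 + D > n) truncated <- truncated + 1L
    m <- cm@cis[[ch[k]]]
    tvals <- c()
    for (d in seq_len(D)) {
      vals <- c(if (t0 + d <= n) m[t0, t0 + d] else NA_real_,
                if (t0 - d >= 1) m[t0 - d, t0] else NA_real_)
      vals <- vals[!is.na(vals)]
      if (length(vals)) {
        sums[d] <- sums[d] + sum(vals)
        cnts[d] <- cnts[d] + length(vals)
        tvals <- c(tvals, vals)
      }
    }
    if (length(tvals)) perTarget[k] <- mean(tvals)
    sub <- .extractWindow(m, t0, t0, D)
    if (!is.null(sub)) state <- .pileAccumulate(state, sub)
  }
  curve <- data.frame(distanceBp = seq_len(D) * bs,
                      value = ifelse(cnts > 0, sums / cnts, NA_real_),
                      n = cnts)
  res <- if (!is.null(state)) {
    new("AggregateResult", matrix = .pileFinish(state),
        nFeatures = length(targets), perFeature = perTarget,
        stats = list(truncated = truncated, maxDistBp = maxDistBp))
  } else {
    new("AggregateResult", matrix = matrix(numeric(0), 0, 0),
        nFeatures = 0L, stats = list(truncated = truncated))
  }
  list(curve = curve, result = res)
}
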