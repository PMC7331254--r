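#' Insulation score
#'
#' For each bin `b`, sums the contact values in the diamond
#' `{(i, j): b - w <= i < b, b < j <= b + w}` (with `w` the window in
#' bins) and reports `log2(diamond sum / chromosome-wide mean diamond
#' sum)`. Bins within `w` of a chromosome end are masked. Insulation
#' minima mark domain boundaries.
#'
#' @param cm a balanced (or count) [ContactMatrix-class].
#' @param windowBp diamond window in bp; must be a multiple of the bin
#'   size and smaller than the chromosome.
#' @return a [BinnedTrack-class].
#' @export
insulationScore <- function(cm, windowBp) {
  grid <- cm@grid
  bs <- binSize(grid)
  if (windowBp <= 0 || windowBp %% bs != 0) {
    .stopf("windowBp must be a positive multiple of the bin size")
  }
  w <- as.integer(windowBp / bs)
  vals <- rep(NA_real_, nBins(grid))
  for (ch in chromNames(grid)) {
    m <- cm@cis[[ch]]
    n <- nrow(m)
    if (n < 2 * w + 1) {
      .stopf("window (%d bins) too large for chromosome %s (%d bins)",
             w, ch, n)
    }
    ds <- rep(NA_real_, n)
    for (b in (w + 1):(n - w)) {
      block <- m[(b - w):(b - 1), (b + 1):(b + w), drop = FALSE]
      if (all(is.na(block))) next
      ds[b] <- sum(block, na.rm = TRUE)
    }
    mu <- mean(ds, na.rm = TRUE)
    vals[grid@offsets[[ch]] + seq_len(n)] <-
      ifelse(!is.na(ds) & ds > 0 & mu > 0, log2(ds / mu), NA_real_)
  }
  BinnedTrack(grid, vals, metadata = list(kind = "insulation",
                                          windowBp = windowBp))
}

#' Call boundaries from an insulation track
#'
#' Local insulation minima whose prominence - the mean of the maxima over
#' the `deltaWindow` bins on each side minus the minimum value - reaches
#' `minDepth` become one-bin boundary intervals. Among equal adjacent
#' minima the leftmost is reported.
#'
#' @param track an insulation [BinnedTrack-class].
#' @param deltaWindow flank width in bins for the prominence computation
#'   (default 10).
#' @param minDepth minimum prominence (default 0.5).
#' @return a [GenomicRanges::GRanges] of one-bin boundaries with a
#'   `prominence` score column.
#' @export
boundariesFromInsulation <- function(track, deltaWindow = 10L,
                                     minDepth = 0.5) {
  grid <- track@grid
  bs <- binSize(grid)
  out <- GRanges()
  for (ch in chromNames(grid)) {
    v <- trackValues(track, ch)
    n <- length(v)
    hits <- integer(0); prom <- numeric(0)
    b <- 2L
    while (b <= n - 1L) {
      if (is.na(v[b])) { b <- b + 1L; next }
      # leftmost point of a minimal plateau
      left <- v[b - 1L]
      right <- v[b + 1L]
      isMin <- !is.na(left) && !is.na(right) && v[b] < left && v[b] <= right
      if (isMin && v[b] == right) {
        # plateau: confirm the value eventually rises on the right
        k <- b + 1L
        while (k <= n && !is.na(v[k]) && v[k] == v[b]) k <- k + 1L
        isMin <- k <= n && !is.na(v[k]) && v[k] > v[b]
      }
      if (isMin) {
        lw <- v[max(1L, b - deltaWindow):(b - 1L)]
        rw <- v[(b + 1L):min(n, b + deltaWindow)]
        if (any(!is.na(lw)) && any(!is.na(rw))) {
          p <- mean(c(max(lw, na.rm = TRUE), max(rw, na.rm = TRUE))) - v[b]
          if (p >= minDepth) {
            hits <- c(hits, b); prom <- c(prom, p)
          }
        }
      }
      b <- b + 1L
    }
    if (length(hits)) {
      out <- c(out, GRanges(ch, IRanges(start = (hits - 1) * bs + 1,
                                        end = pmin(hits * bs,
                                                   chromLengths(grid)[[ch]])),
                            prominence = prom))
    }
  }
  out
}

#' Average track profile around features
#'
#' Mean of track values at bin offsets `-flank..+flank` around each
#' feature midpoint, averaged over features; missing values are excluded
#' per offset. Offsets falling outside a chromosome contribute nothing.
#'
#' @param track a [BinnedTrack-class].
#' @param features a [GenomicRanges::GRanges].
#' @param flankBp flank in bp (rounded down to whole bins).
#' @return a data.frame with columns `offsetBp`, `value`, `n`.
#' @export
averageProfileAt <- function(track, features, flankBp) {
  grid <- track@grid
  bs <- binSize(grid)
  w <- as.integer(flankBp / bs)
  offs <- (-w):w
  sums <- numeric(length(offs)); cnts <- integer(length(offs))
  ch <- as.character(seqnames(features))
  .checkChrom(grid, unique(ch))
  mid0 <- pmin(.mid(features) - 1, chromLengths(grid)[ch] - 1)
  ctr <- localBin(grid, ch, mid0)
  for (k in seq_along(features)) {
    v <- trackValues(track, ch[k])
    idx <- ctr[k] + offs
    ok <- idx >= 1 & idx <= length(v)
    vv <- rep(NA_real_, length(offs))
    vv[ok] <- v[idx[ok]]
    use <- !is.na(vv)
    sums[use] <- sums[use] + vv[use]
    cnts[use] <- cnts[use] + 1L
  }
  data.frame(offsetBp = offs * bs,
             value = ifelse(cnts > 0, sums / cnts, NA_real_),
             n = cnts)
}
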