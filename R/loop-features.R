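#' Classify loops by ChIP-peak occupancy of their anchors
#'
#' For each factor in `peakSets`, calls a loop `both` when both anchors
#' overlap at least one peak (>= 1 bp after padding anchors by `slopBp`),
#' `single` when exactly one does, and `none` when neither does.
#' Enlarging `slopBp` can only move calls from `none` toward `both`.
#'
#' @param loops a [LoopSet-class].
#' @param peakSets named list of [GenomicRanges::GRanges] peak sets.
#' @param slopBp anchor padding in bp (default 0).
#' @return a [S4Vectors::DataFrame] with one `factor_<name>` column of
#'   calls (`both`/`single`/`none`) per peak set, one row per loop.
#' @export
classifyLoops <- function(loops, peakSets, slopBp = 0) {
  if (is.null(names(peakSets)) || any(!nzchar(names(peakSets)))) {
    .stopf("peakSets must be a named list")
  }
  n <- length(loops)
  pad <- function(gr) {
    if (slopBp > 0) {
      GRanges(seqnames(gr), IRanges(start = pmax(1, start(gr) - slopBp),
                                    end = end(gr) + slopBp))
    } else gr
  }
  a1 <- pad(anchorOne(loops))
  a2 <- pad(anchorTwo(loops))
  out <- DataFrame(row.names = seq_len(n))
  for (nm in names(peakSets)) {
    pk <- peakSets[[nm]]
    h1 <- if (length(pk)) countOverlaps(a1, pk) > 0 else rep(FALSE, n)
    h2 <- if (length(pk)) countOverlaps(a2, pk) > 0 else rep(FALSE, n)
    call <- ifelse(h1 & h2, "both", ifelse(h1 | h2, "single", "none"))
    out[[paste0("factor_", nm)]] <- factor(call,
                                           levels = c("both", "single", "none"))
  }
  out
}

#' Select loops by compound occupancy predicates
#'
#' Convenience filter over [classifyLoops()] output, e.g.
#' `selectLoopClass(calls, pol2 = "both", cohesin = "none", ctcf = "none")`
#' for "loops with bound Pol II but without Cohesin or CTCF".
#'
#' @param calls the DataFrame returned by [classifyLoops()].
#' @param ... `factorName = "call"` conditions (call in both/single/none).
#' @return logical vector over loops.
#' @export
selectLoopClass <- function(calls, ...) {
  cond <- list(...)
  keep <- rep(TRUE, nrow(calls))
  for (nm in names(cond)) {
    col <- paste0("factor_", nm)
    if (!col %in% colnames(calls)) .stopf("no occupancy calls for '%s'", nm)
    keep <- keep & (as.character(calls[[col]]) %in% cond[[nm]])
  }
  keep
}

#' Per-loop interaction strength
#'
#' One value per loop from the matrix pixel at the loop's anchor-bin
#' intersection: the center pixel, or the mean of the 3x3 block around it.
#' Masked centers give `NA`.
#'
#' @param cm a [ContactMatrix-class] (O/E or matched-depth counts).
#' @param loops a [LoopSet-class].
#' @param mode `"center_pixel"` or `"center_3x3_mean"`.
#' @return numeric vector, one value per loop.
#' @export
loopStrength <- function(cm, loops,
                         mode = c("center_pixel", "center_3x3_mean")) {
  mode <- match.arg(mode)
  if (length(loops) == 0L) return(numeric(0))
  grid <- cm@grid
  lb <- .loopBins(loops, grid)
  vapply(seq_len(nrow(lb)), function(k) {
    m <- cm@cis[[lb$chrom[k]]]
    n <- nrow(m)
    b1 <- lb$bin1[k]; b2 <- lb$bin2[k]
    if (mode == "center_pixel") {
      v <- m[b1, b2]
      if (is.na(v)) NA_real_ else v
    } else {
      i <- max(1, b1 - 1):min(n, b1 + 1)
      j <- max(1, b2 - 1):min(n, b2 + 1)
      block <- m[i, j]
      if (all(is.na(block))) NA_real_ else mean(block, na.rm = TRUE)
    }
  }, numeric(1))
}

#' Percent change between conditions
#'
#' `100 * (mean(treated) - mean(untreated)) / mean(untreated)`, with an
#' accompanying two-sample test (Student's t or Wilcoxon) and a
#' delta-method standard error. The statistic is scale-invariant and
#' requires a positive untreated mean.
#'
#' @param untreated,treated numeric vectors of per-feature values (`NA`s
#'   dropped; for `paired = TRUE` the vectors must align feature-wise and
#'   pairs with either value missing are dropped).
#' @param test `"t"` or `"wilcoxon"`.
#' @param paired use the paired test and the paired delta-method standard
#'   error (appropriate when the same features are measured in both
#'   conditions, as in a matched-depth depletion contrast; removes
#'   between-feature heterogeneity from the s.e.).
#' @return a list of class `ChangeStat`: `meanUntreated`, `meanTreated`,
#'   `percentChange`, `se` (delta-method s.e. of the percent change,
#'   paired when `paired = TRUE`), `seUnpaired` (the two-sample s.e. of
#'   the same statistic, always reported), `pValue`, `test`, `paired`,
#'   `nUntreated`, `nTreated`.
#' @export
percentChange <- function(untreated, treated, test = c("t", "wilcoxon"),
                          paired = FALSE) {
  test <- match.arg(test)
  if (paired) {
    if (length(untreated) != length(treated)) {
      .stopf("paired percent change requires aligned vectors")
    }
    ok <- !is.na(untreated) & !is.na(treated)
    u <- untreated[ok]
    t_ <- treated[ok]
  } else {
    u <- untreated[!is.na(untreated)]
    t_ <- treated[!is.na(treated)]
  }
  if (!length(u) || !length(t_)) .stopf("empty value set")
  mu <- mean(u); mt <- mean(t_)
  if (mu <= 0) .stopf("percent change undefined: untreated mean <= 0")
  pct <- 100 * (mt - mu) / mu
  # two-sample (between-feature) delta-method s.e. -- the uncertainty of
  # the printed percent-change statistic when the two value sets are
  # treated as independent samples
  vu <- if (length(u) > 1) stats::var(u) / length(u) else 0
  vt <- if (length(t_) > 1) stats::var(t_) / length(t_) else 0
  seUnpaired <- 100 / mu * sqrt(vt + (mt / mu)^2 * vu)
  if (paired && length(u) > 1) {
    # matched features: delta method for the ratio of correlated means
    se <- 100 / mu * sd(t_ - (mt / mu) * u) / sqrt(length(u))
  } else {
    se <- seUnpaired
  }
  p <- NA_real_
  if (length(u) > 1 && length(t_) > 1) {
    p <- tryCatch({
      if (test == "t") t.test(t_, u, paired = paired)$p.value
      else wilcox.test(t_, u, paired = paired, exact = FALSE)$p.value
    }, error = function(e) NA_real_)
  }
  structure(list(meanUntreated = mu, meanTreated = mt, percentChange = pct,
                 se = se, seUnpaired = seUnpaired, pValue = p, test = test,
                 paired = paired,
                 nUntreated = length(u), nTreated = length(t_)),
            class = "ChangeStat")
}

#' @export
print.ChangeStat <- function(x, ...) {
  cat(sprintf("Percent change: %+.2f%% (s.e. %.2f); %s-test p = %s\n",
              x$percentChange, x$se, x$test, format.pval(x$pValue)))
  cat(sprintf("  means: untreated %.4g (n=%d) -> treated %.4g (n=%d)\n",
              x$meanUntreated, x$nUntreated, x$meanTreated, x$nTreated))
  invisible(x)
}

#' Loop strength as a function of loop length
#'
#' Locally weighted regression (tricube weights, degree 1) of per-loop
#' values on loop length, evaluated on a fixed grid, plus binned means as
#' a smoothing-free fallback and a two-group summary at the small/large
#' loop-domain threshold (250 kb).
#'
#' @param loops a [LoopSet-class].
#' @param values per-loop values (same length as `loops`).
#' @param span loess span in (0, 1] (default 0.3).
#' @param nGrid evaluation grid size (default 50).
#' @param splitBp small/large threshold in bp (default 250 kb).
#' @param nBinsFallback number of length bins for the binned means.
#' @return a list with `curve` (length, fitted), `binned` (length bin
#'   midpoint, mean, n), and `twoGroup` (per-group n and mean; groups
#'   `small` = length <= splitBp, `large` = length > splitBp).
#' @export
loopLengthTrend <- function(loops, values, span = 0.3, nGrid = 50L,
                            splitBp = 2.5e5, nBinsFallback = 10L) {
  if (length(values) != length(loops)) {
    .stopf("values must align with loops")
  }
  len <- loopLengths(loops)
  ok <- !is.na(values) & !is.na(len)
  len <- len[ok]; val <- values[ok]
  grp <- factor(ifelse(len <= splitBp, "small", "large"),
                levels = c("small", "large"))
  gm <- tapply(val, grp, mean)   # returned in level order
  twoGroup <- data.frame(group = levels(grp),
                         n = as.integer(table(grp)),
                         mean = as.numeric(gm))
  brk <- seq(min(len), max(len), length.out = nBinsFallback + 1)
  bin <- cut(len, breaks = brk, include.lowest = TRUE)
  binned <- data.frame(length = (head(brk, -1) + tail(brk, -1)) / 2,
                       mean = as.numeric(tapply(val, bin, mean)),
                       n = as.integer(table(bin)))
  curve <- NULL
  if (length(val) >= 10 && length(unique(len)) >= 5) {
    fit <- loess(val ~ len, span = span, degree = 1,
                 family = "gaussian",
                 control = stats::loess.control(surface = "direct"))
    gl <- seq(min(len), max(len), length.out = nGrid)
    curve <- data.frame(length = gl, fitted = predict(fit, newdata =
                                                        data.frame(len = gl)))
  } else {
    .warnf("fewer than 10 loops: returning binned means only")
  }
  list(curve = curve, binned = binned, twoGroup = twoGroup, span = span,
       splitBp = splitBp)
}

#' Rank domains by transcription and split into groups
#'
#' Per-domain score = mean track signal over the domain extended by
#' `flankBp` on each side ([meanSignalOver()]); domains are ranked in
#' decreasing score order (ties broken by coordinate, stably) and cut
#' into `nGroups` equal-size groups, the remainder going to the
#' higher-ranked groups (the tertile remainder rule).
#'
#' @param domains a [GenomicRanges::GRanges].
#' @param track a [BinnedTrack-class] (e.g. nascent-transcription signal).
#' @param flankBp flank in bp (default 100 kb).
#' @param nGroups number of groups (default 2: top/bottom).
#' @return a list with `score` (per domain), `group` (factor, level
#'   `"1"` = highest-signal group) and `order` (ranking permutation).
#' @export
rankDomainsByTranscription <- function(domains, track, flankBp = 1e5,
                                       nGroups = 2L) {
  score <- meanSignalOver(track, domains, flankBp)
  # decreasing score; stable coordinate tie-break
  o <- order(-score, .chromOrder(as.character(seqnames(domains))),
             start(domains))
  n <- length(domains)
  sizes <- rep(floor(n / nGroups), nGroups)
  r <- n - sum(sizes)
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  lab <- rep(seq_len(nGroups), times = sizes)
  grp <- integer(n)
  grp[o] <- lab
  list(score = score, group = factor(grp, levels = seq_len(nGroups)),
       order = o)
}

#' Stitch binding peaks into ranked hotspots (ROSE-style)
#'
#' Peaks whose gaps are at most `stitchBp` are merged into clusters;
#' clusters are ranked by total signal, both rank and signal are scaled to
#' [0, 1], and the cutoff is the point of the ranked curve farthest below
#' the unit-slope diagonal (where the tangent slope equals one). Clusters
#' with signal strictly above the cutoff are hotspots (ties resolve toward
#' fewer hotspots); each hotspot's summit is the midpoint of its
#' strongest constituent peak. The result is invariant to input peak
#' order.
#'
#' @param peaks a [GenomicRanges::GRanges] with a `signal` (or `score`)
#'   column.
#' @param stitchBp maximum stitching gap (default 12500).
#' @return a list with `hotspots` (GRanges of clusters above the cutoff,
#'   with `signal`, `rank` and `summit` columns), `clusters` (all stitched
#'   clusters), and `cutoffSignal`.
#' @export
stitchHotspots <- function(peaks, stitchBp = 12500) {
  if (length(peaks) == 0L) {
    return(list(hotspots = GRanges(), clusters = GRanges(),
                cutoffSignal = NA_real_))
  }
  sig <- mcols(peaks)$signal
  if (is.null(sig)) sig <- mcols(peaks)$score
  if (is.null(sig)) .stopf("peaks need a 'signal' (or 'score') column")
  peaks <- sort(GRanges(seqnames(peaks), IRanges::ranges(peaks),
                        signal = sig))
  cl <- reduce(peaks, min.gapwidth = stitchBp + 1, with.revmap = TRUE)
  rev <- mcols(cl)$revmap
  tot <- vapply(rev, function(ix) sum(mcols(peaks)$signal[ix]), numeric(1))
  summit <- vapply(rev, function(ix) {
    k <- ix[which.max(mcols(peaks)$signal[ix])]
    .mid(peaks[k])
  }, numeric(1))
  mcols(cl)$revmap <- NULL
  mcols(cl)$signal <- tot
  mcols(cl)$summit <- summit
  nc <- length(cl)
  if (nc == 1L) {
    mcols(cl)$rank <- 1L
    return(list(hotspots = cl, clusters = cl, cutoffSignal = NA_real_))
  }
  o <- order(tot)                 # ascending signal
  x <- (seq_len(nc) - 1) / (nc - 1)
  y <- (tot[o] - min(tot)) / max(max(tot) - min(tot), .Machine$double.eps)
  cutIdx <- which.max(x - y)     # farthest below the diagonal
  cutoff <- tot[o][cutIdx]
  hot <- tot > cutoff
  rk <- integer(nc)
  rk[order(-tot)] <- seq_len(nc)
  mcols(cl)$rank <- rk
  list(hotspots = cl[hot][order(mcols(cl)$rank[hot])],
       clusters = cl, cutoffSignal = cutoff)
}

#' Correlate contact changes with genomic signals
#'
#' Pearson and Spearman correlation of per-feature contact changes with
#' one or more per-feature signal vectors; incomplete features are
#' dropped pairwise, and coefficients with fewer than 3 complete pairs
#' are `NA`.
#'
#' @param delta numeric per-feature contact changes.
#' @param signals named list (or data.frame) of numeric vectors aligned
#'   with `delta`.
#' @return data.frame with columns `track`, `pearson`, `spearman`, `n`.
#' @export
changeVsSignalCorrelation <- function(delta, signals) {
  signals <- as.list(signals)
  if (is.null(names(signals)) || any(!nzchar(names(signals)))) {
    .stopf("signals must be named")
  }
  rows <- lapply(names(signals), function(nm) {
    s <- signals[[nm]]
    if (length(s) != length(delta)) .stopf("signal '%s' length mismatch", nm)
    ok <- !is.na(delta) & !is.na(s)
    n <- sum(ok)
    if (n < 3) {
      data.frame(track = nm, pearson = NA_real_, spearman = NA_real_, n = n)
    } else {
      data.frame(track = nm,
                 pearson = cor(delta[ok], s[ok], method = "pearson"),
                 spearman = cor(delta[ok], s[ok], method = "spearman"),
                 n = n)
    }
  })
  do.call(rbind, rows)
}
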