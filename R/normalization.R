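#' Downsample a count matrix to a target sequencing depth
#'
#' Samples `targetTotal` contacts without replacement from the multiset of
#' stored contacts (a multivariate hypergeometric draw across cells), so
#' that matrices from different conditions can be compared at matched
#' depth. Totals are conserved exactly and the draw is reproducible under a
#' fixed seed.
#'
#' @param cm a count [ContactMatrix-class].
#' @param targetTotal number of contacts to retain
#'   (`0 <= targetTotal <= totalContacts(cm)`).
#' @param seed integer seed.
#' @return a count [ContactMatrix-class] with `totalContacts == targetTotal`.
#' @export
downsampleContacts <- function(cm, targetTotal, seed = 1L) {
  if (valueKind(cm) != "count") .stopf("downsampling requires a count matrix")
  total <- totalContacts(cm)
  if (targetTotal < 0 || targetTotal > total) {
    .stopf("targetTotal must be in [0, %s]", format(total))
  }
  if (targetTotal == total) return(cm)
  grid <- cm@grid
  # flatten upper-triangle nonzero cells across chromosomes
  cells <- lapply(chromNames(grid), function(ch) {
    m <- cm@cis[[ch]]
    idx <- which(upper.tri(m, diag = TRUE) & m > 0)
    list(chrom = ch, idx = idx, count = m[idx])
  })
  counts <- unlist(lapply(cells, `[[`, "count"))
  newCounts <- numeric(length(counts))
  if (targetTotal > 0 && length(counts)) {
    cs <- cumsum(counts)
    set.seed(seed)
    picked <- sort(sample.int(total, targetTotal))
    newCounts <- tabulate(findInterval(picked - 1, c(0, cs),
                                       rightmost.closed = FALSE),
                          nbins = length(counts))
  }
  out <- cm
  pos <- 0L
  for (k in seq_along(cells)) {
    ch <- cells[[k]]$chrom
    ni <- length(cells[[k]]$idx)
    m <- matrix(0, nrow(cm@cis[[ch]]), ncol(cm@cis[[ch]]))
    if (ni) {
      m[cells[[k]]$idx] <- newCounts[pos + seq_len(ni)]
      m <- pmax(m, t(m))  # mirror upper triangle to lower
      pos <- pos + ni
    }
    out@cis[[ch]] <- m
  }
  out@totalCount <- targetTotal
  out@metadata$downsampledFrom <- total
  out
}

#' ICE matrix balancing
#'
#' Iterative correction: bins with marginal coverage below
#' `minFrac` of the median nonzero marginal (and, optionally, outliers
#' beyond `madMax` median absolute deviations of the log marginal) are
#' masked, then each cell is repeatedly divided by the product of its two
#' bins' marginal sums (rescaled to mean one) until the coefficient of
#' variation of unmasked marginals falls below `tol` or `maxIter` is
#' reached. Returns per-bin weights `w` such that
#' `balanced(i, j) = count(i, j) * w_i * w_j`.
#'
#' @param cm a count [ContactMatrix-class].
#' @param tol convergence tolerance on the marginal coefficient of
#'   variation (default 1e-7).
#' @param maxIter maximum iterations (default 400).
#' @param minFrac low-coverage cutoff as a fraction of the median nonzero
#'   marginal (default 0.02).
#' @param madMax optional MAD filter on log marginals (`NULL` = off).
#' @return a balanced [ContactMatrix-class] carrying per-bin weights;
#'   masked bins have `NA` weights, rows and columns. Non-convergence
#'   yields a warning and `metadata$converged = FALSE`.
#' @export
iceBalance <- function(cm, tol = 1e-7, maxIter = 400L, minFrac = 0.02,
                       madMax = NULL) {
  if (valueKind(cm) != "count") .stopf("iceBalance requires a count matrix")
  grid <- cm@grid
  out <- cm
  out@valueKind <- "balanced"
  out@weights <- setNames(vector("list", length(chromNames(grid))),
                          chromNames(grid))
  converged <- TRUE
  for (ch in chromNames(grid)) {
    m <- cm@cis[[ch]]
    n <- nrow(m)
    marg <- rowSums(m)
    mask <- marg <= 0
    med <- median(marg[!mask])
    mask <- mask | marg < minFrac * med
    if (!is.null(madMax)) {
      lm <- log(marg[!mask])
      dev <- abs(lm - median(lm)) / max(mad(lm), .Machine$double.eps)
      mask[!mask][dev > madMax] <- TRUE
    }
    if (all(mask)) .stopf("all bins masked on %s", ch)
    keep <- which(!mask)
    w <- rep(NA_real_, n)
    w[keep] <- 1
    mm <- m[keep, keep, drop = FALSE]
    ok <- FALSE
    for (it in seq_len(maxIter)) {
      s <- rowSums(mm)
      cv <- sd(s) / mean(s)
      if (!is.finite(cv)) .stopf("degenerate marginals on %s", ch)
      if (cv < tol) { ok <- TRUE; break }
      s <- s / mean(s)
      mm <- mm / outer(s, s)
      w[keep] <- w[keep] / s
    }
    if (!ok) {
      # one final check after the last division
      s <- rowSums(mm)
      ok <- (sd(s) / mean(s)) < tol
    }
    if (!ok) converged <- FALSE
    bal <- matrix(NA_real_, n, n)
    bal[keep, keep] <- mm
    out@cis[[ch]] <- bal
    out@weights[[ch]] <- w
  }
  if (!converged) .warnf("ICE did not converge to tol within maxIter")
  out@metadata$converged <- converged
  out@metadata$iceTol <- tol
  out
}

#' Expected contact value by genomic distance
#'
#' Per chromosome, `e(d)` is the mean stored value over valid (unmasked)
#' bin pairs at bin distance `d`, for `0 <= d < n`. Distances with no
#' valid pair are `NA`, not zero.
#'
#' @param cm a [ContactMatrix-class] (count or balanced).
#' @return a named list per chromosome, each with numeric `e` (length n,
#'   index `d + 1`) and integer `nPairs`.
#' @export
expectedByDistance <- function(cm) {
  grid <- cm@grid
  out <- setNames(vector("list", length(chromNames(grid))),
                  chromNames(grid))
  for (ch in chromNames(grid)) {
    m <- cm@cis[[ch]]
    n <- nrow(m)
    e <- rep(NA_real_, n)
    np <- integer(n)
    for (d in 0:(n - 1)) {
      i <- seq_len(n - d)
      v <- m[cbind(i, i + d)]
      np[d + 1] <- sum(!is.na(v))
      if (np[d + 1] > 0) e[d + 1] <- mean(v, na.rm = TRUE)
    }
    out[[ch]] <- list(e = e, nPairs = np)
  }
  out
}

#' Observed / expected transform
#'
#' Divides every cell by the expected value at its bin distance,
#' `oe(i, j) = value(i, j) / e(|i - j|)`; cells whose expected value is
#' undefined (or zero) become `NA`. By construction, the per-distance mean
#' of O/E is one for every distance with at least one valid pair.
#'
#' @param cm a [ContactMatrix-class].
#' @param profile an expected profile from [expectedByDistance()]; defaults
#'   to the matrix's own profile.
#' @return an O/E [ContactMatrix-class].
#' @export
observedOverExpected <- function(cm, profile = NULL) {
  grid <- cm@grid
  if (is.null(profile)) profile <- expectedByDistance(cm)
  if (!identical(sort(names(profile)), sort(chromNames(grid)))) {
    .stopf("expected profile does not match the matrix grid")
  }
  out <- cm
  out@valueKind <- "oe"
  for (ch in chromNames(grid)) {
    m <- cm@cis[[ch]]
    n <- nrow(m)
    e <- profile[[ch]]$e
    if (length(e) != n) .stopf("profile length mismatch on %s", ch)
    D <- abs(outer(seq_len(n), seq_len(n), "-"))
    E <- matrix(e[D + 1], n, n)
    E[!is.na(E) & E == 0] <- NA_real_
    out@cis[[ch]] <- m / E
  }
  out
}
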