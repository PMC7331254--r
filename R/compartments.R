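#' A/B compartment eigenvector
#'
#' Per chromosome, computes the leading eigenvector of the correlation
#' matrix of O/E rows over unmasked bins; the sign is oriented so that the
#' eigenvector correlates positively with `orientationTrack` (a GC-content
#' or gene-density proxy that is higher in A-type chromatin). Chromosomes
#' with fewer than `minBins` unmasked bins are skipped with a warning. A
#' chromosome whose leading eigenvalue is not well separated from the
#' second (gap below 10 percent) is flagged low-confidence in the track
#' metadata.
#'
#' @param oe an O/E [ContactMatrix-class].
#' @param orientationTrack a [BinnedTrack-class] on the same grid.
#' @param minBins minimum unmasked bins per chromosome (default 10).
#' @return a [BinnedTrack-class] (PC1; masked bins `NA`) with metadata
#'   `eigenvalues` and `lowConfidence` per chromosome.
#' @export
compartmentEigenvector <- function(oe, orientationTrack, minBins = 10L) {
  if (valueKind(oe) != "oe") .stopf("compartmentEigenvector expects an O/E matrix")
  grid <- oe@grid
  vals <- rep(NA_real_, nBins(grid))
  eig <- list(); lowConf <- logical(0)
  for (ch in chromNames(grid)) {
    m <- oe@cis[[ch]]
    n <- nrow(m)
    keep <- which(colSums(!is.na(m)) > 0)
    if (length(keep) < minBins) {
      .warnf("chromosome %s has < %d usable bins; skipped", ch, minBins)
      next
    }
    a <- m[keep, keep, drop = FALSE]
    # undefined O/E cells sit at their expectation (1) so the dense-BLAS
    # correlation can be used
    a[is.na(a)] <- 1
    cc <- suppressWarnings(cor(a))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    # principal component of the correlation map (columns centered): the
    # centering removes the shared positive baseline that otherwise
    # dominates the leading eigenvector
    pc <- stats::prcomp(cc, center = TRUE, scale. = FALSE)
    v <- pc$rotation[, 1]
    ori <- trackValues(orientationTrack, ch)[keep]
    s <- suppressWarnings(cor(v, ori, use = "complete.obs"))
    if (is.finite(s) && s < 0) v <- -v
    vals[grid@offsets[[ch]] + keep] <- v
    vars <- pc$sdev^2
    eig[[ch]] <- vars[1:min(5, length(vars))]
    gap <- (vars[1] - vars[2]) / max(vars[1], .Machine$double.eps)
    lowConf[ch] <- !is.finite(gap) || gap < 0.1
  }
  BinnedTrack(grid, vals,
              metadata = list(kind = "pc1", eigenvalues = eig,
                              lowConfidence = lowConf))
}

#' Saddle analysis of compartmentalization strength
#'
#' Bins are ranked genome-wide by the compartment eigenvector into
#' `nQuantiles` equal-occupancy groups (group 1 = most B-like, group
#' `nQuantiles` = most A-like). The saddle matrix entry `(q1, q2)` is the
#' mean O/E over cis bin pairs with one bin in each group at bin distance
#' `>= minDistBins`. Compartmentalization strength is the mean of the two
#' same-type corner cells (BB and AA, the extreme quantile cells) divided
#' by the mean of the two cross-type corners.
#'
#' @param oe an O/E [ContactMatrix-class].
#' @param pc1 a [BinnedTrack-class] from [compartmentEigenvector()].
#' @param nQuantiles number of eigenvector groups (default 5, >= 2).
#' @param minDistBins minimum bin distance for counted pairs (default 10;
#'   removes the decay-dominated near-diagonal).
#' @return a list with `saddle` (nQuantiles x nQuantiles matrix),
#'   `strength`, `nQuantiles`, `quantileEdges` and `counts`.
#' @export
saddleAnalysis <- function(oe, pc1, nQuantiles = 5L, minDistBins = 10L) {
  if (nQuantiles < 2L) .stopf("nQuantiles must be >= 2")
  grid <- oe@grid
  pv <- trackValues(pc1)
  valid <- which(!is.na(pv))
  if (!length(valid)) .stopf("eigenvector track is fully masked")
  # equal-occupancy groups by rank
  rk <- rank(pv[valid], ties.method = "first")
  grp <- rep(NA_integer_, length(pv))
  grp[valid] <- as.integer(ceiling(rk / (length(valid) / nQuantiles)))
  grp[valid] <- pmin(grp[valid], nQuantiles)
  edges <- quantile(pv[valid], probs = seq(0, 1, length.out = nQuantiles + 1))
  S <- matrix(0, nQuantiles, nQuantiles)
  Ct <- matrix(0, nQuantiles, nQuantiles)
  for (ch in chromNames(grid)) {
    m <- oe@cis[[ch]]
    n <- nrow(m)
    g <- grp[grid@offsets[[ch]] + seq_len(n)]
    R <- row(m); C <- col(m)
    sel <- which((C - R) >= minDistBins & !is.na(m) &
                 !is.na(g[R]) & !is.na(g[C]))
    if (!length(sel)) next
    gi <- g[R[sel]]; gj <- g[C[sel]]
    id <- (pmin(gi, gj) - 1) * nQuantiles + pmax(gi, gj)
    sums <- tapply(m[sel], id, sum)
    cnts <- tapply(rep(1, length(sel)), id, sum)
    cell <- as.integer(names(sums))
    qi <- floor((cell - 1) / nQuantiles) + 1
    qj <- cell - (qi - 1) * nQuantiles
    S[cbind(qi, qj)] <- S[cbind(qi, qj)] + as.numeric(sums)
    Ct[cbind(qi, qj)] <- Ct[cbind(qi, qj)] + as.numeric(cnts)
    S[cbind(qj, qi)] <- S[cbind(qi, qj)]
    Ct[cbind(qj, qi)] <- Ct[cbind(qi, qj)]
  }
  if (any(rowSums(Ct) == 0)) .stopf("empty eigenvector quantile")
  saddle <- S / Ct
  nq <- nQuantiles
  strength <- ((saddle[1, 1] + saddle[nq, nq]) / 2) /
    ((saddle[1, nq] + saddle[nq, 1]) / 2)
  list(saddle = saddle, strength = strength, nQuantiles = nQuantiles,
       quantileEdges = edges, counts = Ct, minDistBins = minDistBins)
}
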