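# Shared fixtures and independent brute-force oracles.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

toyGrid <- function(nBinsPerChrom = c(chrA = 10L), binBp = 100L) {
  GenomeGrid(nBinsPerChrom * binBp, binBp)
}

# symmetric random matrix wrapped as a single-chromosome ContactMatrix
randomContactMatrix <- function(n, seed = 1, kind = "balanced",
                                integer = FALSE, binBp = 100L) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- if (integer) rpois(sum(ut), 10) else runif(sum(ut), 0.1, 5)
  m <- m + t(m) - diag(diag(m), n)
  grid <- toyGrid(c(chrA = n), binBp)
  ContactMatrix(grid, list(chrA = m), valueKind = kind)
}

# --- independent oracles -------------------------------------------------

# insulation: explicit double loop over the diamond
bruteInsulation <- function(m, w) {
  n <- nrow(m)
  ds <- rep(NA_real_, n)
  for (b in seq_len(n)) {
    if (b - w < 1 || b + w > n) next
    s <- 0
    any_ <- FALSE
    for (i in (b - w):(b - 1)) for (j in (b + 1):(b + w)) {
      if (!is.na(m[i, j])) { s <- s + m[i, j]; any_ <- TRUE }
    }
    if (any_) ds[b] <- s
  }
  mu <- mean(ds, na.rm = TRUE)
  ifelse(!is.na(ds) & ds > 0 & mu > 0, log2(ds / mu), NA_real_)
}

# area-weighted rescale via exact common subdivision (n*out subcells)
bruteRescale <- function(sub, out) {
  n <- nrow(sub)
  k <- out               # each input cell splits into `out` subcells
  big <- sub[rep(seq_len(n), each = k), rep(seq_len(n), each = k)]
  res <- matrix(0, out, out)
  s <- n                 # each output cell covers `n` subcells
  for (p in seq_len(out)) for (q in seq_len(out)) {
    res[p, q] <- mean(big[((p - 1) * s + 1):(p * s),
                          ((q - 1) * s + 1):(q * s)])
  }
  res
}

# per-distance expected by explicit enumeration
bruteExpected <- function(m) {
  n <- nrow(m)
  e <- rep(NA_real_, n)
  for (d in 0:(n - 1)) {
    v <- c()
    for (i in seq_len(n - d)) v <- c(v, m[i, i + d])
    v <- v[!is.na(v)]
    if (length(v)) e[d + 1] <- mean(v)
  }
  e
}

# saddle means by explicit enumeration over cis pairs
bruteSaddle <- function(m, grp, nq, minDist) {
  S <- matrix(0, nq, nq); Ct <- matrix(0, nq, nq)
  n <- nrow(m)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < minDist) next
    if (is.na(m[i, j]) || is.na(grp[i]) || is.na(grp[j])) next
    a <- min(grp[i], grp[j]); b <- max(grp[i], grp[j])
    S[a, b] <- S[a, b] + m[i, j]
    Ct[a, b] <- Ct[a, b] + 1
  }
  S <- S + t(S) - diag(diag(S), nq)
  Ct <- Ct + t(Ct) - diag(diag(Ct), nq)
  out <- S / Ct
  out
}

# PE-SCAn / APA window extraction by explicit indexing
bruteWindow <- function(m, bi, bj, w) {
  n <- nrow(m)
  if (bi - w < 1 || bi + w > n || bj - w < 1 || bj + w > n) return(NULL)
  res <- matrix(NA_real_, 2 * w + 1, 2 * w + 1)
  for (a in -w:w) for (b in -w:w) {
    res[a + w + 1, b + w + 1] <- m[bi + a, bj + b]
  }
  res
}

# ROSE tangent cutoff by explicit scan: the scaled point farthest below
# the unit diagonal
bruteTangentCutoff <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  s[which.max(x - y)]
}

# noiseless intensity wrapped as a ContactMatrix for O/E-based recovery
intensityAsMatrix <- function(truth, perturbed = FALSE) {
  int <- buildIntensity(truth, perturbed = perturbed)
  ContactMatrix(truth@grid, int, valueKind = "balanced")
}

writeTempLines <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
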