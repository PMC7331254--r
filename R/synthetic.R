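#' Simulation configuration for synthetic contact maps
#'
#' Returns the full parameter list of the synthetic Hi-C generator, with
#' every field overridable via `...`. The generator emulates the
#' statistical structure the analysis modules assume: power-law distance
#' decay, a two-compartment checkerboard, self-interacting domains with
#' boundaries, focal loops of three occupancy classes (CTCF/Cohesin-type,
#' Pol II-only, both), promoter-anchored stripes, and clustered
#' polymerase-binding hotspots, each with a multiplicative perturbation
#' factor applied in the "treated" condition, and Poisson-sampled counts
#' at a configurable sequencing depth.
#'
#' Defaults (see the methods vignette for rationale): two 20-Mb
#' chromosomes at 25-kb bins, 2e6 contacts per condition; decay exponent
#' `gamma = 1`, compartment amplitude `alpha = 0.15`, domain boost
#' `beta = 1.6`, loop boost `lambda = 2.5`, stripe boost `sigma = 1.5`,
#' hotspot-pair boost `kappa = 1.4`; all perturbation factors 1
#' (unperturbed).
#'
#' @param ... overrides for any config field.
#' @return a named list of class `hicSimConfig`.
#' @export
simulationConfig <- function(...) {
  cfg <- list(
    version = 1L,
    chromLengths = c(chrS1 = 2e7, chrS2 = 2e7),
    binSize = 25000,
    depth = 2e6,
    seed = 1L,
    gamma = 1.0,
    alpha = 0.15,
    beta = 1.6,
    lambda = 2.5,
    sigma = 1.5,
    kappa = 1.4,
    promoterPairBoost = 1.0,
    overdispersion = 0,
    # feature layout
    compartmentBlockBins = c(40L, 100L),   # 1.0-2.5 Mb blocks at 25 kb
    domainSizeBins = c(12L, 36L),          # 300-900 kb domains
    domainGapBins = c(2L, 8L),
    loopsPerClass = c(ctcf_cohesin = 12L, pol2_only = 12L, both = 6L),
    pol2LoopSepBins = c(7L, 10L),          # 175-250 kb (small loops)
    structuralLoopSepBins = c(12L, 24L),   # 300-600 kb
    stripesPerChrom = 6L,
    stripeExtentBp = 2e5,
    hotspotsPerChrom = 12L,
    hotspotSpacingBins = c(24L, 30L),      # clustered within ~7 Mb
    peaksPerHotspot = c(2L, 4L),
    promotersPerChrom = 36L,
    # perturbation factors (1 = unperturbed)
    factors = list(compartment = 1, domain = 1,
                   loop = c(ctcf_cohesin = 1, pol2_only = 1, both = 1),
                   stripe = 1, hotspot = 1, promoterPair = 1)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) .stopf("unknown config field(s): %s",
                          paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (nm == "factors") {
      f <- over$factors
      badf <- setdiff(names(f), names(cfg$factors))
      if (length(badf)) .stopf("unknown factor field(s): %s",
                               paste(badf, collapse = ", "))
      for (fn in names(f)) {
        if (fn == "loop" && length(f$loop) &&
            !is.null(names(f$loop))) {
          cfg$factors$loop[names(f$loop)] <- f$loop
        } else {
          cfg$factors[[fn]] <- f[[fn]]
        }
      }
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  if (!is.numeric(cfg$depth) || cfg$depth <= 0) {
    .stopf("depth must be > 0")
  }
  if (any(unlist(cfg$factors) < 0)) .stopf("perturbation factors must be >= 0")
  class(cfg) <- "hicSimConfig"
  cfg
}

.runif_int <- function(n, lo, hi) as.integer(floor(runif(n, lo, hi + 1)))

# sample() without the scalar-x surprise
.sampleSafe <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Lay out the ground-truth feature catalog
#'
#' Deterministically (under `config$seed`) places compartment blocks,
#' domains, loops of the three occupancy classes, stripe targets, clustered
#' binding hotspots with constituent peaks, and promoters with activity
#' scores and CTCF flags.
#'
#' @param config a [simulationConfig()] list.
#' @return a [SyntheticTruth-class].
#' @export
synthesizeTruth <- function(config) {
  grid <- GenomeGrid(config$chromLengths, config$binSize)
  set.seed(.childSeed(config$seed, 1L))
  bs <- binSize(grid)
  compart <- character(0)
  domL <- list(); loopL <- list(); stripeL <- list()
  hotL <- list(); peakL <- list(); promL <- list()
  for (ch in chromNames(grid)) {
    n <- nBins(grid, ch)
    # --- compartments: alternating A/B blocks
    lab <- character(0)
    cur <- sample(c("A", "B"), 1)
    while (length(lab) < n) {
      len <- .runif_int(1, config$compartmentBlockBins[1],
                        config$compartmentBlockBins[2])
      lab <- c(lab, rep(cur, len))
      cur <- if (cur == "A") "B" else "A"
    }
    compart <- c(compart, lab[seq_len(n)])
    # --- domains: tiling with gaps
    ds <- integer(0); de <- integer(0)
    pos <- .runif_int(1, 2L, 10L)
    while (TRUE) {
      size <- .runif_int(1, config$domainSizeBins[1], config$domainSizeBins[2])
      if (pos + size > n - 2L) break
      ds <- c(ds, pos); de <- c(de, pos + size - 1L)
      pos <- pos + size + .runif_int(1, config$domainGapBins[1],
                                     config$domainGapBins[2])
    }
    gro <- rep(0L, length(ds))  # marks transcribed domains (set below)
    domIdx <- seq_along(ds)
    # --- loops
    mkAnchor <- function(bin) {
      # 5-kb anchor centred in the bin
      center <- (bin - 1) * bs + bs / 2
      GRanges(ch, IRanges(start = floor(center - 2500) + 1,
                          end = floor(center + 2500)))
    }
    nC <- config$loopsPerClass[["ctcf_cohesin"]]
    nP <- config$loopsPerClass[["pol2_only"]]
    nB <- config$loopsPerClass[["both"]]
    # ctcf_cohesin + both: corner loops of larger domains
    big <- domIdx[(de - ds + 1) >= config$structuralLoopSepBins[1]]
    pickC <- .sampleSafe(big, min(nC + nB, length(big)))
    cls <- c(rep("ctcf_cohesin", min(nC, length(pickC))),
             rep("both", max(0, length(pickC) - nC)))
    for (k in seq_along(pickC)) {
      d <- pickC[k]
      sep <- min(de[d] - ds[d], .runif_int(1, config$structuralLoopSepBins[1],
                                           config$structuralLoopSepBins[2]))
      b1 <- ds[d]
      b2 <- ds[d] + sep
      loopL[[length(loopL) + 1L]] <- list(ch = ch, b1 = b1, b2 = b2,
                                          a1 = mkAnchor(b1), a2 = mkAnchor(b2),
                                          class = cls[k])
    }
    # pol2_only: small loops inside transcribed domains
    host <- .sampleSafe(domIdx[(de - ds + 1) >= config$pol2LoopSepBins[2] + 2],
                        nP, replace = TRUE)
    for (d in unique(host)) gro[d] <- 1L
    for (d in host) {
      sep <- .runif_int(1, config$pol2LoopSepBins[1], config$pol2LoopSepBins[2])
      b1 <- .runif_int(1, ds[d], max(ds[d], de[d] - sep))
      b2 <- min(b1 + sep, n - 1L)
      loopL[[length(loopL) + 1L]] <- list(ch = ch, b1 = b1, b2 = b2,
                                          a1 = mkAnchor(b1), a2 = mkAnchor(b2),
                                          class = "pol2_only")
    }
    domL[[ch]] <- GRanges(ch, IRanges(start = (ds - 1) * bs + 1,
                                      end = de * bs),
                          transcribed = gro)
    # --- stripes: targets inside domains
    sd_ <- .sampleSafe(domIdx, min(config$stripesPerChrom, length(domIdx)))
    stripeBins <- pmin(ds[sd_] + 2L, n)
    stripeL[[ch]] <- if (length(stripeBins)) {
      GRanges(ch, IRanges(start = (stripeBins - 1) * bs + 1,
                          end = stripeBins * bs),
              extent = rep(config$stripeExtentBp, length(stripeBins)))
    } else GRanges(extent = numeric(0))
    # --- hotspots: one cluster of regularly (jittered) spaced summits
    nh <- config$hotspotsPerChrom
    spacing <- .runif_int(nh, config$hotspotSpacingBins[1],
                          config$hotspotSpacingBins[2])
    start0 <- .runif_int(1, 40L, 80L)
    summitBins <- start0 + cumsum(spacing) - spacing[1]
    summitBins <- summitBins[summitBins <= n - 40L]
    summitPos <- (summitBins - 1) * bs + floor(bs / 2)
    hs <- if (length(summitPos)) {
      GRanges(ch, IRanges(start = summitPos - 10000,
                          end = summitPos + 10000),
              summit = summitPos)
    } else GRanges(summit = numeric(0))
    # constituent peaks within each hotspot (for ROSE-style stitching)
    pk <- list()
    for (k in seq_along(summitBins)) {
      np <- .runif_int(1, config$peaksPerHotspot[1], config$peaksPerHotspot[2])
      offs <- sort(c(0, .runif_int(np - 1, -9000L, 9000L)))
      sig <- c(10, runif(np - 1, 1, 5)) * runif(1, 0.8, 1.2)
      pk[[k]] <- GRanges(ch, IRanges(start = summitPos[k] + offs - 400,
                                     end = summitPos[k] + offs + 400),
                         signal = sig, hotspot = k)
    }
    hotL[[ch]] <- hs
    peakL[[ch]] <- .concatGR(pk)
    # --- promoters: active ones at pol2 loop anchors, silent ones random
    pol2Anchors <- unlist(lapply(loopL, function(x)
      if (x$ch == ch && x$class != "ctcf_cohesin") c(x$b1, x$b2) else NULL))
    nProm <- config$promotersPerChrom
    nAct <- min(length(pol2Anchors), floor(nProm / 2))
    actBins <- if (nAct) .sampleSafe(pol2Anchors, nAct) else integer(0)
    silBins <- .sampleSafe(setdiff(seq(5L, n - 5L), actBins), nProm - nAct)
    pb <- c(actBins, silBins)
    act <- c(exp(rnorm(nAct, log(20), 0.5)), exp(rnorm(nProm - nAct,
                                                       log(0.5), 0.5)))
    ctcfB <- runif(nProm) < 0.5
    promPos <- (pb - 1) * bs + floor(bs / 2)
    promL[[ch]] <- GRanges(ch, IRanges(start = promPos - 500,
                                       end = promPos + 500),
                           activity = act, ctcfBound = ctcfB)
  }
  loops <- if (length(loopL)) {
    LoopSet(.concatGR(lapply(loopL, `[[`, "a1")),
            .concatGR(lapply(loopL, `[[`, "a2")),
            class = vapply(loopL, `[[`, "", "class"))
  } else LoopSet(GRanges(), GRanges())
  new("SyntheticTruth",
      grid = grid,
      compartments = factor(compart, levels = c("A", "B")),
      domains = .concatGR(unname(domL)),
      loops = loops,
      stripes = .concatGR(unname(stripeL)),
      hotspots = .concatGR(unname(hotL)),
      peaks = .concatGR(unname(peakL)),
      promoters = .concatGR(unname(promL)),
      params = unclass(config))
}

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(paste0("SyntheticTruth: %d domains, %d loops, %d stripes, ",
                     "%d hotspots, %d promoters\n"),
              length(object@domains), length(object@loops),
              length(object@stripes), length(object@hotspots),
              length(object@promoters)))
})

#' Build the noiseless intensity surfaces
#'
#' Forward model: per chromosome,
#' `mu(i, j) = |i - j|^(-gamma) * c * t * l * s * h`, where the
#' compartment factor `c` is `1 + alpha` for same-label bins and
#' `1 - alpha` otherwise, renormalized per diagonal so the checkerboard is
#' exactly mean-preserving; `t` multiplies `beta` inside a domain; `l`
#' multiplies `lambda * f_loop` on a 3x3 kernel at loop anchor
#' intersections; `s` multiplies `sigma * f_stripe` along stripe rows
#' within the stripe extent; `h` multiplies `kappa * f_hotspot` on 3x3
#' kernels at hotspot-summit pair pixels (pairs within `maxPairSepBp`);
#' boosted promoter pairs multiply `promoterPairBoost * f_promoterPair`.
#' The diagonal uses the `d = 1` decay value (the power law is undefined
#' at `d = 0`; the diagonal is excluded from expected profiles and
#' pile-ups downstream). Overlapping features combine multiplicatively.
#'
#' @param truth a [SyntheticTruth-class].
#' @param perturbed apply the configured perturbation factors
#'   (the "treated" condition)?
#' @param maxPairSepBp hotspot pairs farther apart than this get no boost
#'   (default 10 Mb).
#' @return named list of dense per-chromosome intensity matrices, scaled
#'   to sum to one over the upper triangle (diagonal included).
#' @export
buildIntensity <- function(truth, perturbed = FALSE, maxPairSepBp = 1e7) {
  grid <- truth@grid
  p <- truth@params
  f <- if (perturbed) p$factors else
    list(compartment = 1, domain = 1,
         loop = c(ctcf_cohesin = 1, pol2_only = 1, both = 1),
         stripe = 1, hotspot = 1, promoterPair = 1)
  bs <- binSize(grid)
  out <- setNames(vector("list", length(chromNames(grid))),
                  chromNames(grid))
  lb <- if (length(truth@loops)) .loopBins(truth@loops, grid) else NULL
  loopClass <- if (length(truth@loops)) mcols(truth@loops)$class else character()
  for (ch in chromNames(grid)) {
    n <- nBins(grid, ch)
    D <- abs(outer(seq_len(n), seq_len(n), "-"))
    mu <- pmax(D, 1)^(-p$gamma)
    # compartments (exactly mean-preserving per diagonal)
    lab <- truth@compartments[grid@offsets[[ch]] + seq_len(n)]
    same <- outer(lab, lab, "==")
    alphaEff <- p$alpha * f$compartment
    C <- ifelse(same, 1 + alphaEff, 1 - alphaEff)
    for (d in 0:(n - 1)) {
      i <- seq_len(n - d)
      idx <- cbind(i, i + d)
      mC <- mean(C[idx])
      C[idx] <- C[idx] / mC
      if (d > 0) C[cbind(i + d, i)] <- C[idx]
    }
    mu <- mu * C
    # domains
    dch <- truth@domains[as.character(seqnames(truth@domains)) == ch]
    for (k in seq_along(dch)) {
      rng <- localBin(grid, ch, start(dch)[k] - 1):
        localBin(grid, ch, end(dch)[k] - 1)
      mu[rng, rng] <- mu[rng, rng] * (p$beta * f$domain)
    }
    # loops (3x3 multiplicative kernels, mirrored, clipped; applied
    # in place -- a helper function would copy the dense matrix per call)
    kb1 <- integer(0); kb2 <- integer(0); kf <- numeric(0)
    if (!is.null(lb)) {
      sel <- which(lb$chrom == ch)
      if (length(sel)) {
        kb1 <- c(kb1, lb$bin1[sel]); kb2 <- c(kb2, lb$bin2[sel])
        kf <- c(kf, p$lambda * unlist(f$loop[loopClass[sel]]))
      }
    }
    # stripes
    sch <- truth@stripes[as.character(seqnames(truth@stripes)) == ch]
    for (k in seq_along(sch)) {
      t0 <- localBin(grid, ch, .mid(sch[k]) - 1)
      ext <- floor(mcols(sch)$extent[k] / bs)
      j <- max(1L, t0 - ext):min(n, t0 + ext)
      mu[t0, j] <- mu[t0, j] * (p$sigma * f$stripe)
      mu[j, t0] <- mu[t0, j]
    }
    # hotspot pairs
    hch <- truth@hotspots[as.character(seqnames(truth@hotspots)) == ch]
    if (length(hch) >= 2) {
      hb <- localBin(grid, ch, mcols(hch)$summit)
      cmb <- utils::combn(sort(hb), 2)
      for (k in seq_len(ncol(cmb))) {
        if ((cmb[2, k] - cmb[1, k]) * bs > maxPairSepBp) next
        if (cmb[2, k] - cmb[1, k] < 2) next
        kb1 <- c(kb1, cmb[1, k]); kb2 <- c(kb2, cmb[2, k])
        kf <- c(kf, p$kappa * f$hotspot)
      }
    }
    # boosted promoter pairs: both in top activity tertile and CTCF-bound
    if (p$promoterPairBoost != 1 || f$promoterPair != 1) {
      pch <- truth@promoters[as.character(seqnames(truth@promoters)) == ch]
      if (length(pch) >= 2) {
        hi <- .tertiles(mcols(truth@promoters)$activity)
        hiCh <- hi[as.character(seqnames(truth@promoters)) == ch]
        sel <- which(hiCh == "high" & mcols(pch)$ctcfBound)
        if (length(sel) >= 2) {
          pb <- localBin(grid, ch, .mid(pch[sel]) - 1)
          cmb <- utils::combn(sort(pb), 2)
          for (k in seq_len(ncol(cmb))) {
            sep <- (cmb[2, k] - cmb[1, k]) * bs
            if (sep < 2e5 || sep > 2e6) next
            kb1 <- c(kb1, cmb[1, k]); kb2 <- c(kb2, cmb[2, k])
            kf <- c(kf, p$promoterPairBoost * f$promoterPair)
          }
        }
      }
    }
    for (k in seq_along(kb1)) {
      i <- max(1L, kb1[k] - 1L):min(n, kb1[k] + 1L)
      j <- max(1L, kb2[k] - 1L):min(n, kb2[k] + 1L)
      mu[i, j] <- mu[i, j] * kf[k]
      mu[j, i] <- mu[j, i] * kf[k]
    }
    ut <- upper.tri(mu, diag = TRUE)
    out[[ch]] <- mu / sum(mu[ut])
  }
  # rescale chromosomes to a common total (equal weight per chromosome)
  for (ch in names(out)) out[[ch]] <- out[[ch]] / length(out)
  out
}

# activity tertiles with the remainder going to the higher slices
.tertiles <- function(x) {
  n <- length(x)
  sizes <- rep(floor(n / 3), 3)
  r <- n - sum(sizes)
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  lab <- rep(c("high", "mid", "low"), times = sizes)
  out <- character(n)
  out[order(x, decreasing = TRUE)] <- lab
  factor(out, levels = c("high", "mid", "low"))
}

#' Sample Poisson counts from an intensity surface
#'
#' Counts are drawn independently per upper-triangular cell from a Poisson
#' law with rates scaled so the expected total equals `depth`
#' (a nonzero `overdispersion` switches to a negative binomial with that
#' dispersion). A fixed seed reproduces the draw exactly.
#'
#' @param intensity list of per-chromosome intensity matrices (from
#'   [buildIntensity()]); their upper-triangle sums define cell
#'   probabilities.
#' @param grid the [GenomeGrid-class] the intensities live on.
#' @param depth expected total contact count (> 0).
#' @param seed integer seed.
#' @param overdispersion negative-binomial dispersion (0 = Poisson).
#' @return a count [ContactMatrix-class].
#' @export
sampleCounts <- function(intensity, grid, depth, seed = 1L,
                         overdispersion = 0) {
  if (depth <= 0) .stopf("depth must be > 0")
  totalP <- sum(vapply(intensity, function(m)
    sum(m[upper.tri(m, diag = TRUE)]), numeric(1)))
  set.seed(seed)
  cis <- setNames(vector("list", length(intensity)), names(intensity))
  for (ch in names(intensity)) {
    mu <- intensity[[ch]]
    n <- nrow(mu)
    ut <- upper.tri(mu, diag = TRUE)
    rate <- mu[ut] / totalP * depth
    cnt <- if (overdispersion > 0) {
      stats::rnbinom(length(rate), mu = rate, size = 1 / overdispersion)
    } else {
      rpois(length(rate), rate)
    }
    m <- matrix(0, n, n)
    m[ut] <- cnt
    m <- m + t(m) - diag(diag(m), n)
    cis[[ch]] <- m
  }
  ContactMatrix(grid, cis, valueKind = "count")
}

#' Run a full in-silico depletion experiment
#'
#' Generates matched-depth "untreated" and "treated" count matrices (the
#' treated condition applies the configured perturbation factors), the
#' ground-truth catalog, a nascent-transcription-like track (high over
#' transcribed domains and active promoters), a compartment orientation
#' track (a GC-content-like proxy correlated with A bins), and the ChIP
#' peak sets implied by the loop classes (CTCF, Cohesin, Pol II).
#'
#' @param config a [simulationConfig()] list.
#' @return a list with elements `untreated`, `treated`
#'   ([ContactMatrix-class]), `truth` ([SyntheticTruth-class]), `tracks`
#'   (list of [BinnedTrack-class]: `gro`, `orientation`), `peakSets`
#'   (named list of [GenomicRanges::GRanges]: `ctcf`, `cohesin`, `pol2`)
#'   and `config`.
#' @export
makeExperiment <- function(config = simulationConfig()) {
  truth <- synthesizeTruth(config)
  grid <- truth@grid
  intU <- buildIntensity(truth, perturbed = FALSE)
  intT <- buildIntensity(truth, perturbed = TRUE)
  untreated <- sampleCounts(intU, grid, config$depth,
                            seed = .childSeed(config$seed, 2L),
                            overdispersion = config$overdispersion)
  treated <- sampleCounts(intT, grid, config$depth,
                          seed = .childSeed(config$seed, 3L),
                          overdispersion = config$overdispersion)
  set.seed(.childSeed(config$seed, 4L))
  tracks <- .syntheticTracks(truth)
  peakSets <- .syntheticPeakSets(truth)
  list(untreated = untreated, treated = treated, truth = truth,
       tracks = tracks, peakSets = peakSets, config = config)
}

.syntheticTracks <- function(truth) {
  grid <- truth@grid
  bs <- binSize(grid)
  gro <- abs(rnorm(nBins(grid), 0.1, 0.05))
  # transcribed domains carry elevated nascent signal
  trDom <- truth@domains[mcols(truth@domains)$transcribed == 1L]
  for (k in seq_along(trDom)) {
    ch <- as.character(seqnames(trDom))[k]
    rng <- localBin(grid, ch, start(trDom)[k] - 1):
      localBin(grid, ch, end(trDom)[k] - 1)
    gi <- grid@offsets[[ch]] + rng
    gro[gi] <- gro[gi] + runif(1, 0.8, 1.5)
  }
  # active promoters spike their bin proportionally to activity
  pr <- truth@promoters
  prCh <- as.character(seqnames(pr))
  prBin <- binIndex(grid, prCh, .mid(pr) - 1)
  gro[prBin] <- gro[prBin] + mcols(pr)$activity / 10
  # orientation proxy: noisy GC-like signal higher in A bins
  ori <- 0.42 + 0.03 * (truth@compartments == "A") + rnorm(nBins(grid), 0, 0.005)
  list(gro = BinnedTrack(grid, gro, metadata = list(kind = "gro")),
       orientation = BinnedTrack(grid, ori,
                                 metadata = list(kind = "orientation")))
}

.syntheticPeakSets <- function(truth) {
  loops <- truth@loops
  cls <- mcols(loops)$class
  anchorPeaks <- function(classes) {
    keep <- cls %in% classes
    if (!any(keep)) return(GRanges())
    .concatGR(list(anchorOne(loops)[keep], anchorTwo(loops)[keep]))
  }
  ctcf <- anchorPeaks(c("ctcf_cohesin", "both"))
  # CTCF also at flagged promoters
  pb <- truth@promoters[mcols(truth@promoters)$ctcfBound]
  if (length(pb)) {
    ctcf <- .concatGR(list(ctcf, GRanges(seqnames(pb),
                                         IRanges(start = .mid(pb) - 250,
                                                 end = .mid(pb) + 250))))
  }
  cohesin <- anchorPeaks(c("ctcf_cohesin", "both"))
  pol2 <- .concatGR(list(anchorPeaks(c("pol2_only", "both")), truth@peaks))
  mcols(ctcf) <- NULL; mcols(cohesin) <- NULL
  mcols(pol2) <- NULL
  list(ctcf = sort(ctcf), cohesin = sort(cohesin), pol2 = sort(pol2))
}
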