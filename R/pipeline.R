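#' Read / write simulation configs as YAML
#'
#' @param config a [simulationConfig()] list.
#' @param path YAML file path.
#' @return `writeSimConfig`: `path` invisibly; `readSimConfig`: a
#'   validated config list (unknown keys raise a schema error naming the
#'   offenders).
#' @export
writeSimConfig <- function(config, path) {
  # named vectors must serialize as YAML maps, not bare sequences
  asYaml <- function(x) {
    if (is.list(x)) return(lapply(x, asYaml))
    if (is.factor(x)) return(as.character(x))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  yaml::write_yaml(asYaml(unclass(config)), path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  numVec <- c("chromLengths", "loopsPerClass", "compartmentBlockBins",
              "domainSizeBins", "domainGapBins", "pol2LoopSepBins",
              "structuralLoopSepBins", "hotspotSpacingBins",
              "peaksPerHotspot")
  for (nm in intersect(numVec, names(y))) y[[nm]] <- unlist(y[[nm]])
  if (!is.null(y$factors)) {
    y$factors <- lapply(y$factors, function(x) unlist(x))
  }
  do.call(simulationConfig, y)
}

# stable hash of a config list (via its canonical YAML serialization)
.configHash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeSimConfig(config, tf)
  unname(tools::md5sum(tf))
}

#' Default analysis parameters
#'
#' All knobs of [runAnalyze()], overridable via `...`: insulation window,
#' saddle quantiles and minimum distance, APA window sizes for structural
#' and small loops, PE-SCAn window/separation, stripe reach, and the seed
#' driving depth-matching and permuted backgrounds.
#'
#' @param ... overrides.
#' @return named list.
#' @export
defaultAnalysisParams <- function(...) {
  p <- list(
    seed = 1L,
    insulationWindowBins = 10L,
    boundaryProfileFlankBp = 5e5,
    saddleQuantiles = 5L,
    saddleMinDistBins = 10L,
    metaDomainOutSize = 90L,
    intraDomainMinDistBins = 2L,
    apaHalfWindowBins = 5L,
    smallApaHalfWindowBins = 3L,
    apaCornerSize = 3L,
    peScanWindowBp = 5e5,
    peScanMaxSepBp = 1e7,
    stripeMaxDistBp = 2e5,
    loopSplitBp = 2.5e5,
    transcriptionFlankBp = 1e5,
    doCompartments = TRUE
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) .stopf("unknown analysis parameter(s): %s",
                          paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

#' Simulate an experiment and write it to a directory
#'
#' Runs [makeExperiment()] and writes the full experiment: matrices in the
#' triplet text dialect, feature catalogs as BED/BEDPE, tracks as
#' bedGraph, the ground truth (including parameters and perturbation
#' factors) as JSON, the config as YAML, and a manifest with the config
#' hash and seed.
#'
#' @param config a [simulationConfig()] list.
#' @param dir output directory (created if needed).
#' @return the experiment list, invisibly (with `dir` attached).
#' @export
runSimulate <- function(config = simulationConfig(), dir) {
  exp <- makeExperiment(config)
  writeExperiment(exp, dir)
  exp$dir <- dir
  invisible(exp)
}

#' @rdname runSimulate
#' @param exp an experiment list from [makeExperiment()].
#' @export
writeExperiment <- function(exp, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- exp$truth@grid
  fp <- function(...) file.path(dir, ...)
  writeChromSizes(grid, fp("genome.chrom.sizes"))
  writeContactMatrix(exp$untreated, fp("untreated.matrix"),
                     fp("untreated_abs.bed"))
  writeContactMatrix(exp$treated, fp("treated.matrix"),
                     fp("treated_abs.bed"))
  dom <- exp$truth@domains
  mcols(dom)$name <- ifelse(mcols(dom)$transcribed == 1L,
                            "transcribed", "silent")
  mcols(dom)$score <- mcols(dom)$transcribed
  mcols(dom) <- mcols(dom)[c("name", "score")]
  writeIntervals(dom, fp("domains.bed"))
  loops <- exp$truth@loops
  for (cl in unique(mcols(loops)$class)) {
    writeIntervalPairs(loops[mcols(loops)$class == cl],
                       fp(sprintf("loops_%s.bedpe", cl)))
  }
  writeIntervalPairs(loops, fp("loops_all.bedpe"))
  st <- exp$truth@stripes
  mcols(st)$name <- "stripe"
  mcols(st)$score <- mcols(st)$extent
  mcols(st) <- mcols(st)[c("name", "score")]
  writeIntervals(st, fp("stripes.bed"))
  hs <- exp$truth@hotspots
  mcols(hs)$name <- "hotspot"
  mcols(hs)$score <- mcols(hs)$summit
  mcols(hs) <- mcols(hs)[c("name", "score")]
  writeIntervals(hs, fp("hotspots.bed"))
  pk <- exp$truth@peaks
  mcols(pk)$name <- paste0("peak_hs", mcols(pk)$hotspot)
  mcols(pk)$score <- mcols(pk)$signal
  mcols(pk) <- mcols(pk)[c("name", "score")]
  writeIntervals(pk, fp("binding_peaks.bed"))
  pr <- exp$truth@promoters
  mcols(pr)$name <- ifelse(mcols(pr)$ctcfBound, "ctcf", "no_ctcf")
  mcols(pr)$score <- mcols(pr)$activity
  mcols(pr) <- mcols(pr)[c("name", "score")]
  writeIntervals(pr, fp("promoters.bed"))
  for (nm in names(exp$peakSets)) {
    writeIntervals(exp$peakSets[[nm]], fp(sprintf("peaks_%s.bed", nm)))
  }
  writeTrackBedGraph(exp$tracks$gro, fp("gro.bedgraph"))
  writeTrackBedGraph(exp$tracks$orientation, fp("orientation.bedgraph"))
  writeSimConfig(exp$config, fp("config.yaml"))
  truthJson <- list(
    params = unclass(exp$config),
    compartments = as.character(exp$truth@compartments),
    loopClasses = as.character(mcols(loops)$class)
  )
  jsonlite::write_json(truthJson, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    configHash = unname(tools::md5sum(fp("config.yaml"))),
    seed = exp$config$seed,
    files = sort(list.files(dir))
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an experiment directory back
#'
#' @param dir a directory written by [runSimulate()]/[writeExperiment()].
#' @return an experiment list (`untreated`, `treated`, `truth`, `tracks`,
#'   `peakSets`, `config`, `dir`).
#' @export
readExperiment <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  need <- c("config.yaml", "untreated.matrix", "treated.matrix",
            "untreated_abs.bed", "treated_abs.bed", "truth.json")
  miss <- need[!file.exists(fp(need))]
  if (length(miss)) .stopf("experiment directory %s is missing: %s", dir,
                           paste(miss, collapse = ", "))
  config <- readSimConfig(fp("config.yaml"))
  grid <- GenomeGrid(config$chromLengths, config$binSize)
  untreated <- readContactMatrix(fp("untreated.matrix"),
                                 fp("untreated_abs.bed"), grid)
  treated <- readContactMatrix(fp("treated.matrix"),
                               fp("treated_abs.bed"), grid)
  tj <- jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
  loops <- readIntervalPairs(fp("loops_all.bedpe"), grid)
  loops <- LoopSet(anchorOne(loops), anchorTwo(loops),
                   class = tj$loopClasses)
  domBed <- readIntervals(fp("domains.bed"), grid)
  mcols(domBed)$transcribed <- as.integer(mcols(domBed)$score)
  stBed <- readIntervals(fp("stripes.bed"), grid)
  mcols(stBed)$extent <- mcols(stBed)$score
  hsBed <- readIntervals(fp("hotspots.bed"), grid)
  mcols(hsBed)$summit <- mcols(hsBed)$score
  pkBed <- readIntervals(fp("binding_peaks.bed"), grid)
  mcols(pkBed)$signal <- mcols(pkBed)$score
  prBed <- readIntervals(fp("promoters.bed"), grid)
  mcols(prBed)$activity <- mcols(prBed)$score
  mcols(prBed)$ctcfBound <- mcols(prBed)$name == "ctcf"
  truth <- new("SyntheticTruth", grid = grid,
               compartments = factor(tj$compartments, levels = c("A", "B")),
               domains = domBed, loops = loops, stripes = stBed,
               hotspots = hsBed, peaks = pkBed, promoters = prBed,
               params = unclass(config))
  peakSets <- list()
  for (nm in c("ctcf", "cohesin", "pol2")) {
    f <- fp(sprintf("peaks_%s.bed", nm))
    if (file.exists(f)) peakSets[[nm]] <- readIntervals(f, grid)
  }
  tracks <- list(gro = trackFromBedGraph(fp("gro.bedgraph"), grid),
                 orientation = trackFromBedGraph(fp("orientation.bedgraph"),
                                                 grid))
  list(untreated = untreated, treated = treated, truth = truth,
       tracks = tracks, peakSets = peakSets, config = config, dir = dir)
}

#' Analyze an in-silico depletion experiment
#'
#' The full comparison pipeline between the untreated and treated contact
#' maps: sequencing-depth matching (both conditions downsampled to the
#' smaller total), ICE balancing, O/E transforms, compartment eigenvector
#' and saddle strength, insulation and boundary meta-profiles,
#' meta-domain pile-up and intra-domain enrichment with a Wilcoxon
#' comparison, PE-SCAn around hotspot-summit pairs with a permuted
#' background and a percent-change statistic on matched-depth counts,
#' per-occupancy-class loop percent changes (Student's t), APA corner
#' ratios, the loop-length two-group contrast, transcription-ranked
#' domain changes, stripe decay curves, and change-vs-signal
#' correlations. Every number in the report traces to one exported
#' module function.
#'
#' @param exp an experiment list from [makeExperiment()] /
#'   [readExperiment()], or an experiment directory path.
#' @param params a [defaultAnalysisParams()] list.
#' @return a nested report list (see Details); `report$params` echoes the
#'   parameters.
#' @export
runAnalyze <- function(exp, params = defaultAnalysisParams()) {
  if (is.character(exp)) exp <- readExperiment(exp)
  configHash <- .configHash(exp$config)
  truth <- exp$truth
  grid <- truth@grid
  bs <- binSize(grid)
  report <- list(params = params, configHash = configHash)

  ## depth matching
  tU <- totalContacts(exp$untreated)
  tT <- totalContacts(exp$treated)
  target <- min(tU, tT)
  u <- downsampleContacts(exp$untreated, target, seed = .childSeed(params$seed, 11L))
  t_ <- downsampleContacts(exp$treated, target, seed = .childSeed(params$seed, 12L))
  report$depth <- list(untreatedTotal = tU, treatedTotal = tT,
                       matchedTo = target)

  ## balancing + O/E
  bu <- iceBalance(u)
  bt <- iceBalance(t_)
  oeU <- observedOverExpected(bu)
  oeT <- observedOverExpected(bt)

  ## compartments + saddle
  if (isTRUE(params$doCompartments)) {
    pcU <- compartmentEigenvector(oeU, exp$tracks$orientation)
    pcT <- compartmentEigenvector(oeT, exp$tracks$orientation)
    # each condition is ranked by its own eigenvector: ranking bins by the
    # other condition's (noisy) PC1 would bias its corners upward only
    # there, so only the symmetric design leaves the strengths comparable
    sadU <- saddleAnalysis(oeU, pcU, params$saddleQuantiles,
                           params$saddleMinDistBins)
    sadT <- saddleAnalysis(oeT, pcT, params$saddleQuantiles,
                           params$saddleMinDistBins)
    sadP <- tryCatch(wilcox.test(as.vector(sadU$saddle),
                                 as.vector(sadT$saddle),
                                 paired = TRUE, exact = FALSE)$p.value,
                     error = function(e) NA_real_)
    report$compartments <- list(
      strengthUntreated = sadU$strength,
      strengthTreated = sadT$strength,
      saddleUntreated = sadU$saddle,
      saddleTreated = sadT$saddle,
      wilcoxonP = sadP,
      pc1SignAgreement = .pc1Agreement(pcU, truth))
  }

  ## insulation + boundaries
  insW <- params$insulationWindowBins * bs
  insU <- insulationScore(bu, insW)
  insT <- insulationScore(bt, insW)
  bounds <- .domainBoundaries(truth, grid)
  profU <- averageProfileAt(insU, bounds, params$boundaryProfileFlankBp)
  profT <- averageProfileAt(insT, bounds, params$boundaryProfileFlankBp)
  ctr <- which(profU$offsetBp == 0)
  report$insulation <- list(
    boundaryProfileUntreated = profU,
    boundaryProfileTreated = profT,
    boundaryInsulationUntreated = profU$value[ctr],
    boundaryInsulationTreated = profT$value[ctr],
    nBoundaries = length(bounds))

  ## meta-domain + intra-domain enrichment
  mdU <- metaDomainPileup(oeU, truth@domains, params$metaDomainOutSize)
  mdT <- metaDomainPileup(oeT, truth@domains, params$metaDomainOutSize)
  ideU <- intraDomainEnrichment(oeU, truth@domains,
                                params$intraDomainMinDistBins)
  ideT <- intraDomainEnrichment(oeT, truth@domains,
                                params$intraDomainMinDistBins)
  report$domains <- list(
    metaCentralThirdUntreated = aggregateStats(mdU)$centralThirdMean,
    metaCentralThirdTreated = aggregateStats(mdT)$centralThirdMean,
    intraTad = percentChange(ideU, ideT, test = "wilcoxon"),
    perDomainUntreated = ideU, perDomainTreated = ideT)

  ## hotspot PE-SCAn (matched-depth counts)
  summits <- .hotspotSummits(truth)
  psU <- peScan(u, summits, windowBp = params$peScanWindowBp,
                maxSepBp = params$peScanMaxSepBp,
                seed = .childSeed(params$seed, 21L))
  psT <- peScan(t_, summits, windowBp = params$peScanWindowBp,
                maxSepBp = params$peScanMaxSepBp,
                seed = .childSeed(params$seed, 21L))
  hotChange <- if (nFeatures(psU) && nFeatures(psT)) {
    percentChange(perFeatureValues(psU), perFeatureValues(psT),
                  test = "t", paired = TRUE)
  } else NULL
  report$hotspots <- list(
    change = hotChange,
    nPairs = nFeatures(psU),
    centerEnrichmentUntreated = aggregateStats(psU)$centerEnrichment,
    centerEnrichmentTreated = aggregateStats(psT)$centerEnrichment,
    backgroundCenterEnrichment =
      aggregateStats(psU)$backgroundCenterEnrichment)

  ## per-class loop changes (matched-depth counts, 3x3 means)
  loops <- truth@loops
  lsU <- loopStrength(u, loops, mode = "center_3x3_mean")
  lsT <- loopStrength(t_, loops, mode = "center_3x3_mean")
  cls <- as.character(mcols(loops)$class)
  report$loopClasses <- lapply(split(seq_along(cls), cls), function(ix) {
    percentChange(lsU[ix], lsT[ix], test = "t", paired = TRUE)
  })
  report$loopsAll <- percentChange(lsU, lsT, test = "t", paired = TRUE)

  ## APA
  sepBins <- floor(loopLengths(loops) / bs)
  big <- sepBins > 2L * params$apaHalfWindowBins
  small <- cls == "pol2_only"
  apaU <- loopApa(oeU, loops[big], params$apaHalfWindowBins,
                  params$apaCornerSize)
  apaT <- loopApa(oeT, loops[big], params$apaHalfWindowBins,
                  params$apaCornerSize)
  sapaU <- loopApa(oeU, loops[small], params$smallApaHalfWindowBins,
                   params$apaCornerSize)
  sapaT <- loopApa(oeT, loops[small], params$smallApaHalfWindowBins,
                   params$apaCornerSize)
  smallApaChange <- if (nFeatures(sapaU) && nFeatures(sapaT)) {
    percentChange(perFeatureValues(sapaU), perFeatureValues(sapaT),
                  test = "t", paired = TRUE)
  } else NULL
  report$apa <- list(
    cornerRatioUntreated = aggregateStats(apaU)$cornerRatio,
    cornerRatioTreated = aggregateStats(apaT)$cornerRatio,
    smallLoopCornerRatioUntreated = aggregateStats(sapaU)$cornerRatio,
    smallLoopCornerRatioTreated = aggregateStats(sapaT)$cornerRatio,
    smallLoopChange = smallApaChange)

  ## loop-length trend: two-group percent change
  lenGrp <- ifelse(loopLengths(loops) <= params$loopSplitBp,
                   "small", "large")
  report$loopLength <- lapply(split(seq_along(cls), lenGrp), function(ix) {
    percentChange(lsU[ix], lsT[ix], test = "t", paired = TRUE)
  })

  ## transcription-ranked domains
  rk <- rankDomainsByTranscription(truth@domains, exp$tracks$gro,
                                   params$transcriptionFlankBp, 2L)
  idU <- intraDomainEnrichment(u, truth@domains,
                               params$intraDomainMinDistBins)
  idT <- intraDomainEnrichment(t_, truth@domains,
                               params$intraDomainMinDistBins)
  report$transcriptionGroups <- lapply(split(seq_along(rk$group),
                                             rk$group), function(ix) {
    percentChange(idU[ix], idT[ix], test = "t", paired = TRUE)
  })
  names(report$transcriptionGroups) <- c("top", "bottom")

  ## stripes
  spU <- stripeProfile(oeU, truth@stripes, params$stripeMaxDistBp)
  spT <- stripeProfile(oeT, truth@stripes, params$stripeMaxDistBp)
  stripeChange <- if (nFeatures(spU$result) && nFeatures(spT$result)) {
    percentChange(perFeatureValues(spU$result),
                  perFeatureValues(spT$result), test = "t", paired = TRUE)
  } else NULL
  report$stripes <- list(
    curveUntreated = spU$curve,
    curveTreated = spT$curve,
    meanEnrichmentUntreated = mean(spU$curve$value, na.rm = TRUE),
    meanEnrichmentTreated = mean(spT$curve$value, na.rm = TRUE),
    change = stripeChange)

  ## change-vs-signal correlation at hotspot pairs
  if (nFeatures(psU) >= 3) {
    delta <- perFeatureValues(psT) - perFeatureValues(psU)
    sig <- .hotspotPairSignals(truth, exp$tracks$gro, grid,
                               params$peScanWindowBp,
                               params$peScanMaxSepBp)
    if (!is.null(sig) && nrow(sig) == length(delta)) {
      report$correlations <- changeVsSignalCorrelation(
        delta, list(chip = sig$chip, gro = sig$gro))
    }
  }
  report
}

# fraction of bins where PC1 sign matches the A/B truth (after orientation)
.pc1Agreement <- function(pc1, truth) {
  v <- trackValues(pc1)
  lab <- truth@compartments
  ok <- !is.na(v)
  if (!any(ok)) return(NA_real_)
  mean((v[ok] > 0) == (lab[ok] == "A"))
}

.domainBoundaries <- function(truth, grid) {
  d <- truth@domains
  c(GRanges(seqnames(d), IRanges(start = start(d), width = 1)),
    GRanges(seqnames(d), IRanges(start = end(d), width = 1)))
}

.hotspotSummits <- function(truth) {
  hs <- truth@hotspots
  GRanges(seqnames(hs), IRanges(start = mcols(hs)$summit,
                                end = mcols(hs)$summit + 1))
}

# per hotspot-pair signals (mean constituent-peak signal and GRO around
# the two summits), ordered exactly like peScan's pair enumeration
.hotspotPairSignals <- function(truth, gro, grid, windowBp, maxSepBp) {
  summits <- .hotspotSummits(truth)
  bs <- binSize(grid)
  pairs <- .anchorPairs(grid, summits, floor(maxSepBp / bs),
                        max(1L, as.integer(ceiling(windowBp / bs))))
  if (is.null(pairs)) return(NULL)
  hs <- truth@hotspots
  hsCh <- as.character(seqnames(hs))
  hsBin <- localBin(grid, hsCh, mcols(hs)$summit)
  pkSig <- vapply(seq_along(hs), function(k) {
    sel <- as.character(seqnames(truth@peaks)) == hsCh[k] &
      mcols(truth@peaks)$hotspot == k
    s <- mcols(truth@peaks)$signal[sel]
    if (length(s)) mean(s) else NA_real_
  }, numeric(1))
  groAt <- function(ch, bin) {
    v <- trackValues(gro, ch)
    v[pmax(1, pmin(length(v), bin))]
  }
  chip <- numeric(nrow(pairs)); grov <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    m1 <- which(hsCh == pairs$chrom[k] & hsBin == pairs$bin1[k])
    m2 <- which(hsCh == pairs$chrom[k] & hsBin == pairs$bin2[k])
    chip[k] <- mean(c(pkSig[m1], pkSig[m2]), na.rm = TRUE)
    grov[k] <- mean(c(groAt(pairs$chrom[k], pairs$bin1[k]),
                      groAt(pairs$chrom[k], pairs$bin2[k])))
  }
  data.frame(chip = chip, gro = grov)
}

#' Write an analysis report
#'
#' Serializes a [runAnalyze()] report to `report.json` plus TSVs for the
#' tabular parts (boundary profiles, stripe curves, loop-class changes).
#'
#' @param report a report list.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(.reportToJson(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cc <- .changeTable(report)
  if (!is.null(cc)) {
    utils::write.table(cc, file.path(dir, "changes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (nm in c("boundaryProfileUntreated", "boundaryProfileTreated")) {
    df <- report$insulation[[nm]]
    if (!is.null(df)) {
      utils::write.table(df, file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}

.changeStatToList <- function(x) {
  if (is.null(x)) return(NULL)
  x[c("meanUntreated", "meanTreated", "percentChange", "se", "seUnpaired",
      "pValue", "test", "paired", "nUntreated", "nTreated")]
}

.reportToJson <- function(report) {
  conv <- function(x) {
    if (inherits(x, "ChangeStat")) return(.changeStatToList(x))
    if (is.matrix(x)) return(apply(x, 1, as.numeric, simplify = FALSE))
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, conv))
    x
  }
  conv(report)
}

.changeTable <- function(report) {
  rows <- list()
  add <- function(name, cs) {
    if (is.null(cs)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      set = name, percentChange = cs$percentChange, se = cs$se,
      pValue = cs$pValue, n = cs$nUntreated)
  }
  for (nm in names(report$loopClasses)) {
    add(paste0("loops_", nm), report$loopClasses[[nm]])
  }
  add("loops_all", report$loopsAll)
  add("hotspot_pairs", report$hotspots$change)
  add("intra_tad", report$domains$intraTad)
  add("small_loop_apa", report$apa$smallLoopChange)
  add("stripes", report$stripes$change)
  for (nm in names(report$loopLength)) {
    add(paste0("loops_length_", nm), report$loopLength[[nm]])
  }
  for (nm in names(report$transcriptionGroups)) {
    add(paste0("domains_gro_", nm), report$transcriptionGroups[[nm]])
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Compare recovered changes with the injected truth
#'
#' For each perturbed feature class, compares the analysis report's
#' recovered percent change with the change implied by the injected
#' perturbation factor (`100 * (f - 1)`).
#'
#' @param report a [runAnalyze()] report.
#' @param truth the matching [SyntheticTruth-class] (or experiment list).
#' @return data.frame with columns `class`, `injectedFactor`,
#'   `expectedChangePct`, `recoveredChangePct`, `absErrorPct`.
#' @export
runRecover <- function(report, truth) {
  if (is.list(truth) && !is.null(truth$truth)) truth <- truth$truth
  if (!is.null(report$configHash)) {
    th <- .configHash(truth@params)
    if (!identical(report$configHash, th)) {
      .stopf("report and truth come from different experiments (config hash mismatch)")
    }
  }
  f <- truth@params$factors
  rows <- list()
  add <- function(class, fac, cs) {
    rec <- if (is.null(cs)) NA_real_ else cs$percentChange
    rows[[length(rows) + 1L]] <<- data.frame(
      class = class, injectedFactor = fac,
      expectedChangePct = 100 * (fac - 1),
      recoveredChangePct = rec,
      absErrorPct = abs(rec - 100 * (fac - 1)))
  }
  for (cl in names(f$loop)) {
    add(paste0("loop_", cl), f$loop[[cl]], report$loopClasses[[cl]])
  }
  add("hotspot", f$hotspot, report$hotspots$change)
  add("domain", f$domain, report$domains$intraTad)
  do.call(rbind, rows)
}
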