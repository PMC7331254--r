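#' GenomeGrid: a fixed binning of a genome
#'
#' A `GenomeGrid` defines the coordinate system shared by all contact
#' matrices, tracks and feature sets in the package: an ordered set of
#' chromosomes with their lengths, tiled left to right into half-open
#' `[start, end)` bins of a fixed width (the last bin of a chromosome may be
#' short). Bin ids are 1-based and dense, ordered by (chromosome, start).
#'
#' @slot chromNames ordered chromosome identifiers.
#' @slot chromLengths chromosome lengths in bp, named by chromosome.
#' @slot binSize bin width in bp.
#' @slot binsPerChrom number of bins per chromosome, named.
#' @slot offsets 0-based global bin offset per chromosome, named.
#'
#' @seealso [GenomeGrid()], [binIndex()], [gridBins()]
#' @export
setClass("GenomeGrid",
  representation(
    chromNames = "character",
    chromLengths = "numeric",
    binSize = "numeric",
    binsPerChrom = "integer",
    offsets = "numeric"
  )
)

setValidity("GenomeGrid", function(object) {
  msg <- character()
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize <= 0) {
    msg <- c(msg, "binSize must be a single positive number")
  }
  if (anyDuplicated(object@chromNames)) {
    msg <- c(msg, "duplicated chromosome names")
  }
  if (!identical(names(object@chromLengths), object@chromNames)) {
    msg <- c(msg, "chromLengths names must match chromNames")
  }
  if (any(object@chromLengths <= 0)) {
    msg <- c(msg, "chromosome lengths must be positive")
  }
  exp_bins <- as.integer(ceiling(object@chromLengths / object@binSize))
  if (!identical(unname(object@binsPerChrom), exp_bins)) {
    msg <- c(msg, "binsPerChrom inconsistent with lengths and binSize")
  }
  exp_off <- cumsum(c(0, as.numeric(object@binsPerChrom)))
  exp_off <- exp_off[seq_along(object@chromNames)]
  if (!isTRUE(all.equal(unname(object@offsets), exp_off))) {
    msg <- c(msg, "offsets inconsistent with binsPerChrom")
  }
  if (length(msg)) msg else TRUE
})

#' BinnedTrack: one value per grid bin
#'
#' A per-bin numeric signal (insulation score, compartment eigenvector,
#' nascent-transcription coverage, ChIP coverage, ...) on a [GenomeGrid].
#' Bins with no data carry `NA` ("masked"), which is distinct from zero
#' signal.
#'
#' @slot grid the [GenomeGrid].
#' @slot values numeric vector, one element per global bin; `NA` = masked.
#' @slot metadata free-form list (e.g. eigenvalues, source file).
#' @export
setClass("BinnedTrack",
  representation(grid = "GenomeGrid", values = "numeric", metadata = "list")
)

setValidity("BinnedTrack", function(object) {
  total <- sum(object@grid@binsPerChrom)
  if (length(object@values) != total) {
    return(sprintf("values length %d != total bin count %d",
                   length(object@values), total))
  }
  TRUE
})

#' ContactMatrix: per-chromosome binned contact maps
#'
#' Symmetric per-chromosome (cis) matrices of binned contact values on a
#' shared [GenomeGrid]. `valueKind` records the processing stage: `"count"`
#' (raw integers), `"balanced"` (after [iceBalance()]) or `"oe"`
#' (observed/expected, after [observedOverExpected()]). Masked bins hold
#' `NA` rows/columns. Trans (inter-chromosomal) contacts are retained only
#' as a depth statistic.
#'
#' @slot grid the [GenomeGrid].
#' @slot cis named list of dense symmetric matrices, one per chromosome.
#' @slot valueKind one of `"count"`, `"balanced"`, `"oe"`.
#' @slot totalCount sum of stored cis counts (for counts), else the raw
#'   total of the matrix the values derive from.
#' @slot transCount number of trans contacts seen at binning time.
#' @slot weights named list of per-bin balancing weight vectors (may be empty).
#' @slot metadata free-form list (e.g. convergence flag).
#' @export
setClass("ContactMatrix",
  representation(
    grid = "GenomeGrid",
    cis = "list",
    valueKind = "character",
    totalCount = "numeric",
    transCount = "numeric",
    weights = "list",
    metadata = "list"
  )
)

setValidity("ContactMatrix", function(object) {
  msg <- character()
  if (!object@valueKind %in% c("count", "balanced", "oe")) {
    msg <- c(msg, "valueKind must be 'count', 'balanced' or 'oe'")
  }
  if (!identical(names(object@cis), object@grid@chromNames)) {
    msg <- c(msg, "cis list names must equal grid chromosome names")
  } else {
    for (ch in object@grid@chromNames) {
      m <- object@cis[[ch]]
      n <- object@grid@binsPerChrom[[ch]]
      if (!is.matrix(m) || nrow(m) != n || ncol(m) != n) {
        msg <- c(msg, sprintf("matrix for %s is not %d x %d", ch, n, n))
        next
      }
      if (any(m < 0, na.rm = TRUE)) {
        msg <- c(msg, sprintf("negative values in %s", ch))
      }
      if (!isTRUE(all.equal(m, t(m)))) {
        msg <- c(msg, sprintf("matrix for %s is not symmetric", ch))
      }
    }
    if (object@valueKind == "count") {
      for (ch in object@grid@chromNames) {
        v <- object@cis[[ch]]
        if (any(v[!is.na(v)] != floor(v[!is.na(v)]))) {
          msg <- c(msg, sprintf("count matrix for %s holds non-integers", ch))
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' LoopSet: interval pairs on one chromosome per pair
#'
#' Chromatin loops or promoter pairs: two anchors per element, both on the
#' same chromosome, canonically ordered so that the first anchor's midpoint
#' is not to the right of the second's. Per-loop metadata (strength, class
#' labels, occupancy calls) lives in `elementMetadata`.
#'
#' @slot anchor1,anchor2 parallel [GenomicRanges::GRanges] of anchors.
#' @slot elementMetadata a [S4Vectors::DataFrame] of per-loop columns.
#' @export
setClass("LoopSet",
  representation(
    anchor1 = "GRanges",
    anchor2 = "GRanges",
    elementMetadata = "DataFrame"
  )
)

setValidity("LoopSet", function(object) {
  msg <- character()
  if (length(object@anchor1) != length(object@anchor2)) {
    msg <- c(msg, "anchor vectors differ in length")
  } else if (length(object@anchor1)) {
    if (!all(as.character(GenomicRanges::seqnames(object@anchor1)) ==
             as.character(GenomicRanges::seqnames(object@anchor2)))) {
      msg <- c(msg, "trans pairs are not allowed in a LoopSet")
    }
    m1 <- .mid(object@anchor1)
    m2 <- .mid(object@anchor2)
    if (any(m1 > m2)) {
      msg <- c(msg, "anchors not in canonical order (midpoint1 <= midpoint2)")
    }
  }
  if (nrow(object@elementMetadata) != length(object@anchor1)) {
    msg <- c(msg, "elementMetadata row count must equal loop count")
  }
  if (length(msg)) msg else TRUE
})

#' AggregateResult: a pile-up matrix with its bookkeeping
#'
#' The output of pile-up operators ([metaDomainPileup()], [peScan()],
#' [loopApa()], [promoterPairAggregate()], [stripeProfile()]): the averaged
#' matrix, the number of contributing features, an optional background
#' matrix (e.g. permuted anchors), optional per-feature center values for
#' downstream statistics, and summary statistics.
#'
#' @slot matrix the averaged pile-up.
#' @slot nFeatures number of features (windows / pairs) contributing.
#' @slot background optional background matrix of the same shape.
#' @slot perFeature optional numeric vector of per-feature center values.
#' @slot stats named list of summaries (center enrichment, corner ratio,
#'   skip counts, parameters).
#' @export
setClass("AggregateResult",
  representation(
    matrix = "matrix",
    nFeatures = "integer",
    background = "ANY",
    perFeature = "ANY",
    stats = "list"
  ),
  prototype(background = NULL, perFeature = NULL, stats = list())
)

setValidity("AggregateResult", function(object) {
  msg <- character()
  if (object@nFeatures > 0L && length(object@matrix) == 0L) {
    msg <- c(msg, "non-empty result requires a matrix")
  }
  if (!is.null(object@background) &&
      !identical(dim(object@background), dim(object@matrix))) {
    msg <- c(msg, "background shape differs from matrix")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: the generator's ground-truth catalog
#'
#' Everything the synthetic contact-map generator embedded, with the
#' perturbation factor applied to each feature class in the "treated"
#' condition. Used by parameter-recovery analyses.
#'
#' @slot grid the [GenomeGrid].
#' @slot compartments factor of "A"/"B" labels per global bin.
#' @slot domains [GenomicRanges::GRanges] of self-interacting domains.
#' @slot loops [LoopSet] with a `class` column
#'   (`ctcf_cohesin`, `pol2_only`, `both`).
#' @slot stripes [GenomicRanges::GRanges] of stripe targets with an
#'   `extent` column (bp).
#' @slot hotspots [GenomicRanges::GRanges] of stitched binding hotspots;
#'   `summit` column gives the summit position.
#' @slot peaks [GenomicRanges::GRanges] of constituent binding peaks with
#'   `signal` scores.
#' @slot promoters [GenomicRanges::GRanges] with `activity` and `ctcfBound`
#'   columns.
#' @slot params the full generator parameter list (boosts, decay exponent,
#'   perturbation factors, seed).
#' @export
setClass("SyntheticTruth",
  representation(
    grid = "GenomeGrid",
    compartments = "factor",
    domains = "GRanges",
    loops = "LoopSet",
    stripes = "GRanges",
    hotspots = "GRanges",
    peaks = "GRanges",
    promoters = "GRanges",
    params = "list"
  )
)
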