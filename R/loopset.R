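#' Construct a LoopSet
#'
#' Pairs of anchors (loops, promoter pairs) on the same chromosome. Anchors
#' are swapped into canonical order (first-anchor midpoint <= second-anchor
#' midpoint). Trans pairs raise an error; use [readIntervalPairs()] to drop
#' them with a warning instead.
#'
#' @param anchor1,anchor2 parallel [GenomicRanges::GRanges].
#' @param ... per-loop metadata columns (e.g. `strength =`), each of the
#'   same length as the anchors.
#' @return a [LoopSet-class].
#' @export
LoopSet <- function(anchor1, anchor2, ...) {
  if (length(anchor1) != length(anchor2)) {
    .stopf("anchor1 and anchor2 differ in length")
  }
  meta <- DataFrame(..., check.names = FALSE)
  if (ncol(meta) == 0L) meta <- S4Vectors::make_zero_col_DFrame(length(anchor1))
  if (length(anchor1)) {
    if (!all(as.character(seqnames(anchor1)) ==
             as.character(seqnames(anchor2)))) {
      .stopf("trans pairs not allowed in a LoopSet")
    }
    swap <- .mid(anchor2) < .mid(anchor1)
    if (any(swap)) {
      a1 <- anchor1
      anchor1[swap] <- anchor2[swap]
      anchor2[swap] <- a1[swap]
    }
  }
  new("LoopSet", anchor1 = anchor1, anchor2 = anchor2,
      elementMetadata = meta)
}

#' @describeIn LoopSet-class first (left) anchor ranges.
#' @param x a LoopSet.
#' @export
setMethod("anchorOne", "LoopSet", function(x) x@anchor1)

#' @describeIn LoopSet-class second (right) anchor ranges.
#' @export
setMethod("anchorTwo", "LoopSet", function(x) x@anchor2)

#' @describeIn LoopSet-class loop length in bp (anchor midpoint separation).
#' @export
setMethod("loopLengths", "LoopSet", function(x) {
  .mid(x@anchor2) - .mid(x@anchor1)
})

#' @export
setMethod("length", "LoopSet", function(x) length(x@anchor1))

#' @describeIn LoopSet-class per-loop metadata columns.
#' @export
setMethod("mcols", "LoopSet", function(x, ...) x@elementMetadata)

#' @export
setMethod("[", "LoopSet", function(x, i, j, ..., drop = TRUE) {
  new("LoopSet", anchor1 = x@anchor1[i], anchor2 = x@anchor2[i],
      elementMetadata = x@elementMetadata[i, , drop = FALSE])
})

setMethod("show", "LoopSet", function(object) {
  cat(sprintf("LoopSet with %d pair(s)", length(object)))
  if (ncol(object@elementMetadata)) {
    cat(sprintf("; metadata: %s",
                paste(colnames(object@elementMetadata), collapse = ", ")))
  }
  cat("\n")
  if (length(object)) {
    n <- min(3L, length(object))
    for (i in seq_len(n)) {
      cat(sprintf("  %s:%d-%d <-> %d-%d\n",
                  as.character(seqnames(object@anchor1))[i],
                  start(object@anchor1)[i], end(object@anchor1)[i],
                  start(object@anchor2)[i], end(object@anchor2)[i]))
    }
    if (length(object) > n) cat("  ...\n")
  }
})

# anchor midpoint bins (local, per chromosome) for a LoopSet on a grid
.loopBins <- function(loops, grid) {
  ch <- as.character(seqnames(anchorOne(loops)))
  .checkChrom(grid, unique(ch))
  # midpoints are 1-based closed coords; convert to 0-based for binning
  b1 <- localBin(grid, ch, pmin(.mid(anchorOne(loops)) - 1,
                                grid@chromLengths[ch] - 1))
  b2 <- localBin(grid, ch, pmin(.mid(anchorTwo(loops)) - 1,
                                grid@chromLengths[ch] - 1))
  data.frame(chrom = ch, bin1 = pmin(b1, b2), bin2 = pmax(b1, b2),
             stringsAsFactors = FALSE)
}
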