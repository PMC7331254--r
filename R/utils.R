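#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   mcols<- findOverlaps countOverlaps reduce resize shift sort.GenomicRanges
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors DataFrame queryHits subjectHits
#' @importFrom data.table fread fwrite data.table setnames :=
NULL

# midpoint (floor) of a GRanges, 1-based coordinates
.mid <- function(gr) {
  floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
}

# full-precision numeric formatting for text writers (round-trip exact)
.fmtNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# concatenate GRanges whose seqlevels may differ (merge is intentional)
.concatGR <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) return(GRanges())
  suppressWarnings(do.call(c, lst))
}
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# frame (outermost one-pixel ring) mean of a matrix
.frameMean <- function(m) {
  n <- nrow(m)
  if (n <= 2L) return(mean(m, na.rm = TRUE))
  ring <- c(m[1, ], m[n, ], m[2:(n - 1), 1], m[2:(n - 1), n])
  mean(ring, na.rm = TRUE)
}

# derive a child seed (< 2^31) from a base seed and a stream index
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k * 7919) %% 2147483647)
}
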