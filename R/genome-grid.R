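#' Build a genome grid
#'
#' Constructs the fixed coordinate system used by all contact matrices and
#' tracks: each chromosome is tiled left to right into half-open
#' `[start, end)` bins of `binSize` bp; the last bin may be short.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp); the
#'   name order defines the chromosome order.
#' @param binSize bin width in bp (> 0).
#' @return a [GenomeGrid-class] object.
#' @examples
#' grid <- GenomeGrid(c(chrA = 1e6, chrB = 5e5), binSize = 1e5)
#' nBins(grid)
#' @export
GenomeGrid <- function(chromLengths, binSize) {
  if (is.null(names(chromLengths)) || any(!nzchar(names(chromLengths)))) {
    .stopf("chromLengths must be named by chromosome")
  }
  binSize <- as.numeric(binSize)
  if (length(binSize) != 1L || is.na(binSize) || binSize <= 0) {
    .stopf("binSize must be a single positive number")
  }
  lens <- as.numeric(chromLengths)
  names(lens) <- names(chromLengths)
  nb <- as.integer(ceiling(lens / binSize))
  off <- cumsum(c(0, as.numeric(nb)))[seq_along(lens)]
  names(off) <- names(lens)
  names(nb) <- names(lens)
  new("GenomeGrid", chromNames = names(lens), chromLengths = lens,
      binSize = binSize, binsPerChrom = nb, offsets = off)
}

#' Read a chrom.sizes file
#'
#' Two-column tab-separated file of chromosome name and length. Chromosome
#' naming is taken verbatim (no "chr" normalization).
#'
#' @param path file path.
#' @param binSize bin width in bp for the resulting grid.
#' @return a [GenomeGrid-class].
#' @export
readChromSizes <- function(path, binSize) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 2L) .stopf("chrom.sizes must have 2 columns: %s", path)
  lens <- as.numeric(dt[[2]])
  names(lens) <- as.character(dt[[1]])
  GenomeGrid(lens, binSize)
}

#' Write a chrom.sizes file
#' @param grid a [GenomeGrid-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeChromSizes <- function(grid, path) {
  lines <- sprintf("%s\t%s", chromNames(grid),
                   .fmtNum(chromLengths(grid)))
  writeLines(lines, path)
  invisible(path)
}

#' @describeIn GenomeGrid-class ordered chromosome names.
#' @param x a GenomeGrid.
#' @export
setMethod("chromNames", "GenomeGrid", function(x) x@chromNames)

#' @describeIn GenomeGrid-class named chromosome lengths (bp).
#' @export
setMethod("chromLengths", "GenomeGrid", function(x) x@chromLengths)

#' @describeIn GenomeGrid-class bin width (bp).
#' @export
setMethod("binSize", "GenomeGrid", function(x) x@binSize)

#' @describeIn GenomeGrid-class total bin count, or per-chromosome count
#'   when `chrom` is given.
#' @param chrom optional chromosome name.
#' @export
setMethod("nBins", "GenomeGrid", function(x, chrom = NULL) {
  if (is.null(chrom)) return(sum(x@binsPerChrom))
  .checkChrom(x, chrom)
  unname(x@binsPerChrom[chrom])
})

setMethod("show", "GenomeGrid", function(object) {
  cat(sprintf("GenomeGrid: %d chromosome(s), bin size %s bp, %d bins\n",
              length(object@chromNames), format(object@binSize),
              sum(object@binsPerChrom)))
  cat(" ", paste(sprintf("%s (%s bp)", object@chromNames,
                         format(object@chromLengths)), collapse = ", "),
      "\n")
})

.checkChrom <- function(grid, chrom) {
  bad <- setdiff(chrom, grid@chromNames)
  if (length(bad)) {
    .stopf("chromosome(s) not on grid: %s", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Map genomic positions to bin indices
#'
#' Within a chromosome, position `p` (0-based) falls in local bin
#' `floor(p / binSize) + 1`. `binIndex` returns global (genome-wide dense)
#' 1-based bin ids; `localBin` returns the 1-based bin within a chromosome.
#'
#' @param grid a [GenomeGrid-class].
#' @param chrom chromosome name(s), recycled against `pos`.
#' @param pos 0-based positions in `[0, chromosome length)`.
#' @return integer bin ids.
#' @export
binIndex <- function(grid, chrom, pos) {
  k <- localBin(grid, chrom, pos)
  as.integer(grid@offsets[chrom] + k)
}

#' @rdname binIndex
#' @export
localBin <- function(grid, chrom, pos) {
  .checkChrom(grid, unique(chrom))
  if (any(pos < 0 | pos >= grid@chromLengths[chrom])) {
    .stopf("position outside chromosome")
  }
  as.integer(floor(pos / grid@binSize) + 1)
}

#' Bins of a grid as GRanges
#'
#' @param grid a [GenomeGrid-class].
#' @param chrom optional single chromosome; default all.
#' @return a [GenomicRanges::GRanges] of the half-open bins (stored 1-based
#'   closed, i.e. bin `[s, e)` in 0-based becomes `start = s + 1, end = e`).
#' @export
gridBins <- function(grid, chrom = NULL) {
  chs <- if (is.null(chrom)) chromNames(grid) else chrom
  .checkChrom(grid, chs)
  parts <- lapply(chs, function(ch) {
    n <- grid@binsPerChrom[[ch]]
    s0 <- (seq_len(n) - 1) * grid@binSize
    e0 <- pmin(s0 + grid@binSize, grid@chromLengths[[ch]])
    GRanges(ch, IRanges(start = s0 + 1, end = e0))
  })
  do.call(c, parts)
}

# order feature rows by (grid chromosome order, start); chroms not on the
# grid sort after, alphabetically
.chromOrder <- function(chrom, grid = NULL) {
  if (!is.null(grid)) {
    lev <- c(chromNames(grid), setdiff(sort(unique(chrom)), chromNames(grid)))
  } else {
    lev <- unique(sort(unique(chrom)))
  }
  factor(chrom, levels = lev)
}
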