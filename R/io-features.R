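#' Read genomic intervals from BED
#'
#' Reads BED3/BED6 (or broadPeak-like files with extra columns; the first
#' six columns are interpreted as chrom, start, end, name, score, strand).
#' Coordinates are 0-based half-open on disk and stored 1-based closed in
#' the returned `GRanges`. Intervals are returned sorted by
#' (chromosome, start); with a `grid`, chromosome order follows the grid
#' and intervals on chromosomes absent from the grid are dropped with a
#' warning.
#'
#' @param path BED file path.
#' @param grid optional [GenomeGrid-class] used for chromosome order and
#'   filtering.
#' @param dropOffGrid drop intervals on unknown chromosomes (default TRUE
#'   when a grid is given); if FALSE, unknown chromosomes raise an error.
#' @return a [GenomicRanges::GRanges] with optional `name` and `score`
#'   metadata columns.
#' @export
readIntervals <- function(path, grid = NULL, dropOffGrid = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(GRanges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L)) {
    .stopf("malformed BED line %d in %s: fewer than 3 fields",
           lineNo[which(ncols < 3L)[1]], path)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(s) || anyNA(e)) {
    .stopf("malformed BED line %d in %s: non-numeric coordinates",
           lineNo[which(is.na(s) | is.na(e))[1]], path)
  }
  bad <- s >= e | s < 0
  if (any(bad)) {
    .stopf("invalid interval at line %d in %s: start >= end (or < 0)",
           lineNo[which(bad)[1]], path)
  }
  name <- if (any(ncols >= 4L)) {
    vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else NA_character_, "")
  } else NULL
  score <- if (any(ncols >= 5L)) {
    suppressWarnings(as.numeric(vapply(parts, function(p)
      if (length(p) >= 5L) p[[5L]] else NA_character_, "")))
  } else NULL
  if (!is.null(grid)) {
    off <- !chrom %in% chromNames(grid)
    if (any(off)) {
      if (!dropOffGrid) {
        .stopf("interval chromosome(s) absent from grid: %s",
               paste(unique(chrom[off]), collapse = ", "))
      }
      .warnf("dropped %d interval(s) on chromosomes absent from grid (%s)",
             sum(off), paste(unique(chrom[off]), collapse = ", "))
      chrom <- chrom[!off]; s <- s[!off]; e <- e[!off]
      if (!is.null(name)) name <- name[!off]
      if (!is.null(score)) score <- score[!off]
    }
    over <- chromLengths(grid)[chrom] < e
    if (any(over)) .stopf("interval end beyond chromosome length (%s)",
                          chrom[which(over)[1]])
  }
  o <- order(.chromOrder(chrom, grid), s)
  gr <- GRanges(chrom[o], IRanges(start = s[o] + 1, end = e[o]))
  if (!is.null(name)) mcols(gr)$name <- name[o]
  if (!is.null(score)) mcols(gr)$score <- score[o]
  gr
}

#' Write intervals as BED
#'
#' Emits sorted, tab-separated, newline-terminated BED records (0-based
#' half-open); `name`/`score` metadata columns become BED columns 4-5,
#' written at full precision so a read/write round trip is exact.
#'
#' @param gr a [GenomicRanges::GRanges].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIntervals <- function(gr, path) {
  o <- order(.chromOrder(as.character(seqnames(gr))), start(gr))
  gr <- gr[o]
  chrom <- as.character(seqnames(gr))
  s <- start(gr) - 1
  e <- end(gr)
  cols <- list(chrom, .fmtNum(s), .fmtNum(e))
  md <- mcols(gr)
  if (!is.null(md$name) || !is.null(md$score)) {
    nm <- if (is.null(md$name)) rep(".", length(gr)) else as.character(md$name)
    cols <- c(cols, list(nm))
    if (!is.null(md$score)) cols <- c(cols, list(.fmtNum(md$score)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read interval pairs from BEDPE
#'
#' BEDPE with at least six columns (chrom1 start1 end1 chrom2 start2 end2;
#' column 7 is taken as a name, column 8 as a numeric strength if present).
#' Anchors are put in canonical order; trans pairs are counted and excluded
#' with a warning; anchors on chromosomes absent from `grid` raise an error.
#'
#' @param path BEDPE path.
#' @param grid optional [GenomeGrid-class] to validate chromosomes against.
#' @return a [LoopSet-class].
#' @export
readIntervalPairs <- function(path, grid = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(LoopSet(GRanges(), GRanges()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 6L)) {
    .stopf("malformed BEDPE line %d in %s: fewer than 6 fields",
           lineNo[which(lengths(parts) < 6L)[1]], path)
  }
  g <- function(k) vapply(parts, `[[`, "", k)
  num <- function(k) {
    v <- suppressWarnings(as.numeric(g(k)))
    if (anyNA(v)) .stopf("malformed BEDPE line %d in %s",
                         lineNo[which(is.na(v))[1]], path)
    v
  }
  c1 <- g(1); s1 <- num(2); e1 <- num(3)
  c2 <- g(4); s2 <- num(5); e2 <- num(6)
  if (any(s1 >= e1 | s2 >= e2)) {
    .stopf("invalid anchor at line %d in %s: start >= end",
           lineNo[which(s1 >= e1 | s2 >= e2)[1]], path)
  }
  if (!is.null(grid)) {
    bad <- !(c1 %in% chromNames(grid)) | !(c2 %in% chromNames(grid))
    if (any(bad)) {
      .stopf("anchor chromosome(s) absent from grid at line %d in %s",
             lineNo[which(bad)[1]], path)
    }
  }
  trans <- c1 != c2
  if (any(trans)) {
    .warnf("excluded %d trans pair(s) in %s", sum(trans), path)
  }
  ok <- !trans
  strength <- if (any(lengths(parts) >= 8L)) {
    suppressWarnings(as.numeric(vapply(parts, function(p)
      if (length(p) >= 8L) p[[8L]] else NA_character_, "")))
  } else NULL
  a1 <- GRanges(c1[ok], IRanges(start = s1[ok] + 1, end = e1[ok]))
  a2 <- GRanges(c2[ok], IRanges(start = s2[ok] + 1, end = e2[ok]))
  if (is.null(strength)) LoopSet(a1, a2)
  else LoopSet(a1, a2, strength = strength[ok])
}

#' Write interval pairs as BEDPE
#' @param loops a [LoopSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIntervalPairs <- function(loops, path) {
  a1 <- anchorOne(loops); a2 <- anchorTwo(loops)
  n <- length(loops)
  cols <- list(as.character(seqnames(a1)), .fmtNum(start(a1) - 1),
               .fmtNum(end(a1)), as.character(seqnames(a2)),
               .fmtNum(start(a2) - 1), .fmtNum(end(a2)))
  md <- mcols(loops)
  if (!is.null(md$strength)) {
    cols <- c(cols, list(rep(".", n), .fmtNum(md$strength)))
  }
  lines <- if (n) do.call(paste, c(cols, sep = "\t")) else character()
  writeLines(lines, path)
  invisible(path)
}

#' Construct a BinnedTrack
#' @param grid a [GenomeGrid-class].
#' @param values numeric, one per global bin (`NA` = masked). A single
#'   value is recycled.
#' @param metadata optional list.
#' @return a [BinnedTrack-class].
#' @export
BinnedTrack <- function(grid, values = NA_real_, metadata = list()) {
  total <- nBins(grid)
  if (length(values) == 1L) values <- rep(as.numeric(values), total)
  new("BinnedTrack", grid = grid, values = as.numeric(values),
      metadata = metadata)
}

#' @describeIn BinnedTrack-class underlying grid.
#' @param x a BinnedTrack.
#' @export
setMethod("genomeGrid", "BinnedTrack", function(x) x@grid)

#' @describeIn BinnedTrack-class values (all bins, or one chromosome).
#' @param chrom optional chromosome name.
#' @export
setMethod("trackValues", "BinnedTrack", function(x, chrom = NULL) {
  if (is.null(chrom)) return(x@values)
  .checkChrom(x@grid, chrom)
  off <- x@grid@offsets[[chrom]]
  x@values[off + seq_len(x@grid@binsPerChrom[[chrom]])]
})

setMethod("show", "BinnedTrack", function(object) {
  v <- object@values
  cat(sprintf("BinnedTrack on %d bins (%d masked); range [%s, %s]\n",
              length(v), sum(is.na(v)),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE)))))
})

#' Bin a bedGraph signal onto a grid
#'
#' Each bin aggregates the bedGraph records overlapping it: `mean` is
#' bp-weighted over the covered base pairs, `sum` adds each record's value
#' pro-rated by the fraction of the record inside the bin (so splitting a
#' record at a bin edge changes nothing), `max` takes the maximum record
#' value. Bins covered by no record are masked (`NA`).
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open).
#' @param grid a [GenomeGrid-class].
#' @param aggregation one of `"mean"`, `"sum"`, `"max"`.
#' @return a [BinnedTrack-class].
#' @export
trackFromBedGraph <- function(path, grid,
                              aggregation = c("mean", "sum", "max")) {
  aggregation <- match.arg(aggregation)
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "value")[1:4])
  if (ncol(dt) < 4L) .stopf("bedGraph must have 4 columns: %s", path)
  off <- !dt$chrom %in% chromNames(grid)
  if (any(off)) {
    .warnf("skipped %d bedGraph record(s) on chromosomes absent from grid (%s)",
           sum(off), paste(unique(dt$chrom[off]), collapse = ", "))
    dt <- dt[!off, ]
  }
  values <- rep(NA_real_, nBins(grid))
  if (!nrow(dt)) return(BinnedTrack(grid, values))
  if (any(dt$start >= dt$end)) .stopf("bedGraph record with start >= end")
  bs <- binSize(grid)
  # expand each record into the bins it overlaps
  firstBin <- floor(dt$start / bs) + 1
  lastBin <- ceiling(dt$end / bs)
  reps <- as.integer(lastBin - firstBin + 1)
  idx <- rep(seq_len(nrow(dt)), reps)
  bin <- unlist(lapply(seq_len(nrow(dt)),
                       function(i) seq(firstBin[i], lastBin[i])))
  binStart <- (bin - 1) * bs
  ov <- pmin(dt$end[idx], binStart + bs) - pmax(dt$start[idx], binStart)
  gbin <- as.integer(grid@offsets[dt$chrom[idx]] + bin)
  if (any(bin > grid@binsPerChrom[dt$chrom[idx]])) {
    .stopf("bedGraph record beyond chromosome end")
  }
  v <- dt$value[idx]
  if (aggregation == "mean") {
    num <- tapply(v * ov, gbin, sum)
    den <- tapply(ov, gbin, sum)
    values[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  } else if (aggregation == "sum") {
    w <- ov / (dt$end[idx] - dt$start[idx])
    num <- tapply(v * w, gbin, sum)
    values[as.integer(names(num))] <- as.numeric(num)
  } else {
    num <- tapply(v, gbin, max)
    values[as.integer(names(num))] <- as.numeric(num)
  }
  BinnedTrack(grid, values, metadata = list(source = path,
                                            aggregation = aggregation))
}

#' Write a track as bedGraph
#'
#' Masked bins are omitted. Values are written at full precision so a
#' write/read round trip (with `aggregation = "mean"`) is exact.
#'
#' @param track a [BinnedTrack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrackBedGraph <- function(track, path) {
  grid <- track@grid
  lines <- character()
  for (ch in chromNames(grid)) {
    v <- trackValues(track, ch)
    k <- which(!is.na(v))
    if (!length(k)) next
    s <- (k - 1) * binSize(grid)
    e <- pmin(s + binSize(grid), chromLengths(grid)[[ch]])
    lines <- c(lines, sprintf("%s\t%s\t%s\t%s", ch, .fmtNum(s), .fmtNum(e),
                              .fmtNum(v[k])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Mean track signal over an interval with flanks
#'
#' Mean of unmasked bin values across the bins overlapping
#' `[start - flankBp, end + flankBp)`, clipped to the chromosome. Returns
#' `NA` if every bin in the window is masked.
#'
#' @param track a [BinnedTrack-class].
#' @param interval a length-1 [GenomicRanges::GRanges] (or a longer one, in
#'   which case a vector is returned).
#' @param flankBp symmetric flank in bp (>= 0).
#' @return numeric value(s).
#' @export
meanSignalOver <- function(track, interval, flankBp = 0) {
  if (flankBp < 0) .stopf("flankBp must be >= 0")
  grid <- track@grid
  ch <- as.character(seqnames(interval))
  .checkChrom(grid, unique(ch))
  s0 <- pmax(start(interval) - 1 - flankBp, 0)
  e0 <- pmin(end(interval) + flankBp, chromLengths(grid)[ch])
  bs <- binSize(grid)
  vapply(seq_along(interval), function(i) {
    b1 <- floor(s0[i] / bs) + 1
    b2 <- ceiling(e0[i] / bs)
    v <- trackValues(track, ch[i])[b1:b2]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}
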