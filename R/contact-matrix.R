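#' Construct a ContactMatrix
#'
#' @param grid a [GenomeGrid-class].
#' @param cis named list of dense symmetric per-chromosome matrices (one
#'   per grid chromosome; missing chromosomes are filled with zeros).
#' @param valueKind `"count"`, `"balanced"` or `"oe"`.
#' @param totalCount total raw contact count; defaults to the sum of the
#'   cis matrices for counts.
#' @param transCount trans contacts observed at binning time.
#' @param weights optional named list of per-bin balancing weights.
#' @param metadata optional list.
#' @return a [ContactMatrix-class].
#' @export
ContactMatrix <- function(grid, cis = list(), valueKind = "count",
                          totalCount = NA_real_, transCount = 0,
                          weights = list(), metadata = list()) {
  full <- setNames(vector("list", length(chromNames(grid))),
                   chromNames(grid))
  for (ch in chromNames(grid)) {
    n <- grid@binsPerChrom[[ch]]
    m <- cis[[ch]]
    if (is.null(m)) m <- matrix(0, n, n)
    full[[ch]] <- m
  }
  if (is.na(totalCount)) {
    totalCount <- sum(vapply(full, function(m) {
      ut <- m[upper.tri(m, diag = TRUE)]
      sum(ut, na.rm = TRUE)
    }, numeric(1)))
  }
  new("ContactMatrix", grid = grid, cis = full, valueKind = valueKind,
      totalCount = totalCount, transCount = transCount, weights = weights,
      metadata = metadata)
}

#' @describeIn ContactMatrix-class the grid.
#' @param x a ContactMatrix.
#' @export
setMethod("genomeGrid", "ContactMatrix", function(x) x@grid)

#' @describeIn ContactMatrix-class `"count"`, `"balanced"` or `"oe"`.
#' @export
setMethod("valueKind", "ContactMatrix", function(x) x@valueKind)

#' @describeIn ContactMatrix-class total raw contact count.
#' @export
setMethod("totalContacts", "ContactMatrix", function(x) x@totalCount)

#' @describeIn ContactMatrix-class dense symmetric matrix for one
#'   chromosome.
#' @param chrom chromosome name.
#' @export
setMethod("cisMatrix", "ContactMatrix", function(x, chrom) {
  .checkChrom(x@grid, chrom)
  x@cis[[chrom]]
})

#' @describeIn ContactMatrix-class balancing weights (all, or one
#'   chromosome); `NULL` for unbalanced matrices.
#' @export
setMethod("binWeights", "ContactMatrix", function(x, chrom = NULL) {
  if (!length(x@weights)) return(NULL)
  if (is.null(chrom)) return(x@weights)
  x@weights[[chrom]]
})

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf("ContactMatrix [%s] on %d chromosome(s), %s bp bins\n",
              object@valueKind, length(object@cis),
              format(binSize(object@grid))))
  cat(sprintf("  total contacts: %s; trans: %s\n",
              format(object@totalCount), format(object@transCount)))
})

# per-chromosome upper-triangle (incl. diagonal) sum
.cisSum <- function(m) sum(m[upper.tri(m, diag = TRUE)], na.rm = TRUE)

# replace one chromosome's matrix, keeping symmetry
.setCis <- function(cm, chrom, m) {
  cm@cis[[chrom]] <- m
  cm
}

#' Read a 4DN-style pairs file
#'
#' Header lines start with `#`; the seven core columns are readID, chrom1,
#' pos1, chrom2, pos2, strand1, strand2, optionally followed by fragment
#' ids (frag1, frag2). Records are canonically ordered so that end a <=
#' end b by (chromosome, position).
#'
#' @param path pairs file path.
#' @param grid optional [GenomeGrid-class] to validate chromosomes against.
#' @return a `data.table` with columns chrom1, pos1, strand1, chrom2, pos2,
#'   strand2 and optionally frag1, frag2.
#' @export
readPairs <- function(path, grid = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.table(chrom1 = character(), pos1 = numeric(),
                      chrom2 = character(), pos2 = numeric(),
                      strand1 = character(), strand2 = character()))
  }
  dt <- fread(text = paste(lines, collapse = "\n"), header = FALSE,
              sep = "\t")
  if (ncol(dt) < 7L) .stopf("pairs file must have >= 7 columns: %s", path)
  # 4DN positions are 1-based on disk; stored 0-based internally
  out <- data.table(
    chrom1 = as.character(dt[[2]]), pos1 = as.numeric(dt[[3]]) - 1,
    chrom2 = as.character(dt[[4]]), pos2 = as.numeric(dt[[5]]) - 1,
    strand1 = as.character(dt[[6]]), strand2 = as.character(dt[[7]])
  )
  if (ncol(dt) >= 9L) {
    out$frag1 <- as.integer(dt[[8]])
    out$frag2 <- as.integer(dt[[9]])
  }
  if (!is.null(grid)) {
    bad <- unique(c(out$chrom1, out$chrom2))
    bad <- setdiff(bad, chromNames(grid))
    if (length(bad)) .stopf("pairs on chromosome(s) absent from grid: %s",
                            paste(bad, collapse = ", "))
  }
  canonicalizePairs(out)
}

#' @rdname readPairs
#' @param pairs a pairs `data.table`/`data.frame`.
#' @export
canonicalizePairs <- function(pairs) {
  pairs <- data.table::as.data.table(pairs)
  swap <- pairs$chrom1 > pairs$chrom2 |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos1 > pairs$pos2)
  if (any(swap)) {
    cols1 <- intersect(c("chrom1", "pos1", "strand1", "frag1"), names(pairs))
    cols2 <- sub("1$", "2", cols1)
    tmp <- pairs[swap, cols1, with = FALSE]
    for (k in seq_along(cols1)) {
      data.table::set(pairs, which(swap), cols1[k],
                      pairs[[cols2[k]]][swap])
      data.table::set(pairs, which(swap), cols2[k], tmp[[k]])
    }
  }
  pairs
}

#' Filter contact pairs
#'
#' Removes (i) pairs whose two ends fall on the same restriction fragment
#' (covering dangling-end and self-circle ligation classes) and (ii) exact
#' duplicates (identical chromosome, position and strand at both ends; a
#' PCR-artifact proxy). When fragment ids are absent, they are assigned by
#' position lookup in `fragments`.
#'
#' @param pairs a pairs table (see [readPairs()]).
#' @param fragments optional [GenomicRanges::GRanges] of restriction
#'   fragments; required if the table has no frag1/frag2 columns and
#'   `dropSameFragment` is TRUE.
#' @param dropDuplicates remove exact duplicates (default TRUE).
#' @param dropSameFragment remove same-fragment pairs (default TRUE).
#' @return a list with elements `pairs` (the retained table) and `stats`
#'   (named counts: input, retained, duplicate, same_fragment).
#' @export
filterPairs <- function(pairs, fragments = NULL, dropDuplicates = TRUE,
                        dropSameFragment = TRUE) {
  pairs <- data.table::as.data.table(pairs)
  nIn <- nrow(pairs)
  stats <- c(input = nIn, duplicate = 0L, same_fragment = 0L)
  if (nIn == 0L) {
    return(list(pairs = pairs, stats = c(stats, retained = 0L)))
  }
  if (dropDuplicates) {
    key <- paste(pairs$chrom1, pairs$pos1, pairs$strand1,
                 pairs$chrom2, pairs$pos2, pairs$strand2)
    dup <- duplicated(key)
    stats[["duplicate"]] <- sum(dup)
    pairs <- pairs[!dup, ]
  }
  if (dropSameFragment) {
    if (!all(c("frag1", "frag2") %in% names(pairs))) {
      if (is.null(fragments)) {
        .stopf("fragment ids absent and no fragment ranges supplied")
      }
      pairs$frag1 <- .assignFragment(fragments, pairs$chrom1, pairs$pos1)
      pairs$frag2 <- .assignFragment(fragments, pairs$chrom2, pairs$pos2)
    }
    same <- pairs$chrom1 == pairs$chrom2 & pairs$frag1 == pairs$frag2 &
      !is.na(pairs$frag1) & !is.na(pairs$frag2)
    stats[["same_fragment"]] <- sum(same)
    pairs <- pairs[!same, ]
  }
  list(pairs = pairs, stats = c(stats, retained = nrow(pairs)))
}

.assignFragment <- function(fragments, chrom, pos) {
  q <- GRanges(chrom, IRanges(start = pos + 1, width = 1))
  hit <- GenomicRanges::findOverlaps(q, fragments, select = "first")
  as.integer(hit)
}

#' Bin filtered pairs into a count matrix
#'
#' Each cis pair increments one upper-triangular cell (i <= j by bin);
#' trans pairs are counted into the depth statistic only. `totalContacts`
#' equals the number of input pairs.
#'
#' @param pairs a filtered pairs table.
#' @param grid a [GenomeGrid-class].
#' @return a count [ContactMatrix-class].
#' @export
binPairs <- function(pairs, grid) {
  pairs <- data.table::as.data.table(pairs)
  cis <- setNames(lapply(chromNames(grid), function(ch) {
    n <- grid@binsPerChrom[[ch]]
    matrix(0, n, n)
  }), chromNames(grid))
  transCount <- 0
  if (nrow(pairs)) {
    .checkChrom(grid, unique(c(pairs$chrom1, pairs$chrom2)))
    isCis <- pairs$chrom1 == pairs$chrom2
    transCount <- sum(!isCis)
    cp <- pairs[isCis, ]
    if (nrow(cp)) {
      b1 <- localBin(grid, cp$chrom1, cp$pos1)
      b2 <- localBin(grid, cp$chrom2, cp$pos2)
      i <- pmin(b1, b2); j <- pmax(b1, b2)
      for (ch in unique(cp$chrom1)) {
        k <- cp$chrom1 == ch
        n <- grid@binsPerChrom[[ch]]
        counts <- tapply(rep(1, sum(k)), (i[k] - 1) * n + j[k], sum)
        cell <- as.numeric(names(counts))
        ii <- floor((cell - 1) / n) + 1
        jj <- cell - (ii - 1) * n
        m <- cis[[ch]]
        m[cbind(ii, jj)] <- m[cbind(ii, jj)] + as.numeric(counts)
        m[cbind(jj, ii)] <- m[cbind(ii, jj)]
        cis[[ch]] <- m
      }
    }
  }
  ContactMatrix(grid, cis, valueKind = "count",
                totalCount = nrow(pairs), transCount = transCount)
}

#' Read / write contact matrices in the triplet text dialect
#'
#' The interchange format is a pair of text files: a bins file
#' (`_abs.bed`: chrom, start, end, 1-based bin id, tab-separated) and a
#' matrix file of `(bin_id_a, bin_id_b, value)` triplets. Triplets are
#' canonicalized to the upper triangle on read; bin definitions must match
#' the grid's bin width. The writer emits sorted upper-triangular triplets
#' at full precision plus, for balanced matrices, a weights sidecar TSV.
#'
#' @param matrixPath triplet file path.
#' @param binsPath bins (`_abs.bed`) file path.
#' @param grid optional [GenomeGrid-class]; defaults to the grid implied by
#'   the bins file.
#' @param valueKind stored value kind (default `"count"`).
#' @return `readContactMatrix`: a [ContactMatrix-class].
#' @export
readContactMatrix <- function(matrixPath, binsPath, grid = NULL,
                              valueKind = "count") {
  bins <- fread(binsPath, header = FALSE, sep = "\t",
                col.names = c("chrom", "start", "end", "id"))
  implied <- .gridFromBins(bins)
  if (is.null(grid)) {
    grid <- implied
  } else {
    if (!isTRUE(all.equal(binSize(grid), binSize(implied))) ||
        !identical(chromNames(grid), chromNames(implied)) ||
        !isTRUE(all.equal(chromLengths(grid), chromLengths(implied)))) {
      .stopf("bins file does not match the supplied grid")
    }
  }
  trip <- fread(matrixPath, header = FALSE, sep = "\t",
                col.names = c("a", "b", "value"))
  total <- sum(grid@binsPerChrom)
  if (nrow(trip) && (min(trip$a, trip$b) < 1 || max(trip$a, trip$b) > total)) {
    .stopf("triplet bin id outside grid (1..%d)", total)
  }
  cis <- setNames(lapply(chromNames(grid), function(ch) {
    n <- grid@binsPerChrom[[ch]]
    matrix(0, n, n)
  }), chromNames(grid))
  if (nrow(trip)) {
    a <- pmin(trip$a, trip$b)
    b <- pmax(trip$a, trip$b)
    chromOf <- rep(chromNames(grid), grid@binsPerChrom)
    cha <- chromOf[a]; chb <- chromOf[b]
    if (any(cha != chb)) {
      .warnf("skipped %d trans triplet(s)", sum(cha != chb))
      keep <- cha == chb
      a <- a[keep]; b <- b[keep]; trip <- trip[keep, ]; cha <- cha[keep]
    }
    for (ch in unique(cha)) {
      k <- cha == ch
      la <- a[k] - grid@offsets[[ch]]
      lb <- b[k] - grid@offsets[[ch]]
      m <- cis[[ch]]
      m[cbind(la, lb)] <- m[cbind(la, lb)] + trip$value[k]
      m[cbind(lb, la)] <- m[cbind(la, lb)]
      cis[[ch]] <- m
    }
  }
  ContactMatrix(grid, cis, valueKind = valueKind)
}

.gridFromBins <- function(bins) {
  if (is.unsorted(bins$id)) bins <- bins[order(bins$id), ]
  widths <- bins$end - bins$start
  chroms <- unique(bins$chrom)
  lens <- vapply(chroms, function(ch) max(bins$end[bins$chrom == ch]),
                 numeric(1))
  names(lens) <- chroms
  # bin width = modal width (last bin per chromosome may be short)
  bs <- as.numeric(names(sort(table(widths), decreasing = TRUE))[1])
  notLast <- !bins$id %in% vapply(chroms, function(ch)
    max(bins$id[bins$chrom == ch]), numeric(1))
  if (any(widths[notLast] != bs)) {
    .stopf("bins file has non-uniform bin width")
  }
  GenomeGrid(lens, bs)
}

#' @rdname readContactMatrix
#' @param cm a [ContactMatrix-class] to write.
#' @param weightsPath optional path for the balancing-weights sidecar TSV
#'   (chrom, bin, weight); written only if the matrix carries weights.
#' @return `writeContactMatrix`: `matrixPath`, invisibly.
#' @export
writeContactMatrix <- function(cm, matrixPath, binsPath,
                               weightsPath = NULL) {
  grid <- cm@grid
  binLines <- character()
  tripLines <- character()
  for (ch in chromNames(grid)) {
    n <- grid@binsPerChrom[[ch]]
    s <- (seq_len(n) - 1) * binSize(grid)
    e <- pmin(s + binSize(grid), chromLengths(grid)[[ch]])
    ids <- grid@offsets[[ch]] + seq_len(n)
    binLines <- c(binLines, sprintf("%s\t%s\t%s\t%d", ch, .fmtNum(s),
                                    .fmtNum(e), as.integer(ids)))
    m <- cm@cis[[ch]]
    ut <- which(upper.tri(m, diag = TRUE) & !is.na(m) & m != 0,
                arr.ind = TRUE)
    if (nrow(ut)) {
      o <- order(ut[, 1], ut[, 2])
      ut <- ut[o, , drop = FALSE]
      tripLines <- c(tripLines, sprintf("%d\t%d\t%s",
                                        as.integer(grid@offsets[[ch]] + ut[, 1]),
                                        as.integer(grid@offsets[[ch]] + ut[, 2]),
                                        .fmtNum(m[ut])))
    }
  }
  writeLines(binLines, binsPath)
  writeLines(tripLines, matrixPath)
  if (!is.null(weightsPath) && length(cm@weights)) {
    wl <- unlist(lapply(chromNames(grid), function(ch) {
      w <- cm@weights[[ch]]
      sprintf("%s\t%d\t%s", ch, seq_along(w), .fmtNum(w))
    }))
    writeLines(wl, weightsPath)
  }
  invisible(matrixPath)
}
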