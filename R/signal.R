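## From read starts to filtered count matrices. Reads are width-1 GRanges
## marking the 5' base of each alignment (for minus-strand reads this is the
## rightmost aligned base); metadata()$fragLen carries the declared mean
## fragment length.

#' Approximate fragment centers from stranded read starts
#'
#' The center of the sequenced fragment is estimated by shifting each read's
#' 5' position by half the mean fragment length: downstream for plus-strand
#' reads, upstream for minus-strand reads. Centers are clipped to the
#' chromosome when lengths are declared.
#'
#' @param reads width-1 `GRanges` of read 5' positions with strand `+`/`-`;
#'   `metadata(reads)$fragLen` may hold the fragment length.
#' @param fragLen mean fragment length in bp (> 0); defaults to the value
#'   recorded in `metadata(reads)$fragLen`.
#' @return sorted width-1 `GRanges` of center positions.
#' @export
fragmentCenters <- function(reads, fragLen = metadata(reads)$fragLen) {
  stopifnot(is(reads, "GRanges"))
  if (is.null(fragLen) || !is.finite(fragLen) || fragLen <= 0)
    stop("'fragLen' must be a positive fragment length")
  st <- as.character(strand(reads))
  if (any(st == "*")) stop("reads must be stranded (+ or -)")
  half <- round(fragLen / 2)
  pos <- ifelse(st == "+", start(reads) + half, start(reads) - half)
  pos <- pmax(pos, 1L)
  sl <- seqlengths(reads)
  if (!all(is.na(sl))) {
    lim <- sl[as.character(seqnames(reads))]
    pos <- pmin(pos, ifelse(is.na(lim), pos, lim))
  }
  centers <- GRanges(seqnames(reads), IRanges(pos, width = 1L),
                     seqlengths = sl)
  BiocGenerics::sort(centers)
}

#' Randomly downsample a read-start table
#'
#' Uniform sampling without replacement to exactly `targetN` reads, so that
#' libraries entering the tile counts are depth-matched. The retained reads
#' are returned in coordinate order and the sampled depth is recorded as
#' `metadata()$libSize`.
#'
#' @param reads `GRanges` of read starts.
#' @param targetN number of reads to retain; must not exceed `length(reads)`
#'   (no upsampling).
#' @param seed integer seed; the global RNG state is left untouched.
#' @return downsampled `GRanges`.
#' @export
downsampleReads <- function(reads, targetN, seed) {
  stopifnot(is(reads, "GRanges"))
  targetN <- as.integer(targetN)
  if (targetN > length(reads))
    stop("targetN (", targetN, ") exceeds available reads (", length(reads),
         "); upsampling is not supported")
  keep <- withSeed(seed, sample.int(length(reads), targetN))
  out <- BiocGenerics::sort(reads[keep], ignore.strand = TRUE)
  metadata(out) <- metadata(reads)
  metadata(out)$libSize <- targetN
  out
}

#' Call enriched domains by a Poisson sliding window
#'
#' Sliding windows are scored by the upper-tail Poisson p-value of their
#' fragment-center count against the genome-wide mean density; windows
#' significant after Benjamini-Hochberg adjustment are merged into maximal
#' runs. This is a deliberately simple, deterministic segmenter for density
#' "domains"; its window/step/FDR defaults are configuration, not biology.
#'
#' @param centers width-1 `GRanges` of fragment centers with a declared
#'   chromosome length (`seqlengths`).
#' @param window,step window width and step in bp.
#' @param fdr BH threshold on window p-values.
#' @return `GRanges` of called domains (empty if no window is significant).
#' @export
callDomains <- function(centers, window = 2000L, step = 500L, fdr = 0.05) {
  stopifnot(is(centers, "GRanges"))
  if (!length(centers)) return(GRanges())
  sl <- seqlengths(centers)
  if (any(is.na(sl)))
    stop("callDomains() needs chromosome lengths on 'centers'")
  genome <- GRanges(names(sl), IRanges(1L, sl))
  win <- unlist(slidingWindows(genome, width = window, step = step))
  cnt <- countOverlaps(win, centers)
  lambda <- length(centers) * width(win) / sum(as.numeric(sl))
  p <- ppois(cnt - 1L, lambda, lower.tail = FALSE)
  q <- bhAdjust(p)
  GenomicRanges::reduce(win[q < fdr])
}

#' Count fragment centers within tiles
#'
#' Each center increments exactly the tile whose half-open span contains it;
#' centers outside all tiles are not counted.
#'
#' @param centers width-1 `GRanges` of fragment centers.
#' @param tiles sorted, non-overlapping `GRanges` of tiles.
#' @return integer counts named by tile id.
#' @export
countInTiles <- function(centers, tiles) {
  stopifnot(is(centers, "GRanges"), is(tiles, "GRanges"))
  if (!IRanges::isDisjoint(tiles, ignore.strand = TRUE))
    stop("tiles must be non-overlapping")
  setNames(countOverlaps(tiles, centers, ignore.strand = TRUE),
           tileIds(tiles))
}

#' Assemble a TileCounts object from per-sample center sets
#'
#' @param centerList named list of center `GRanges`, one per sample.
#' @param tiles tile `GRanges` (from [tileDomains()]).
#' @param condition,libSize per-sample metadata; `libSize` defaults to each
#'   sample's `metadata()$libSize` (set by [downsampleReads()]) or its total
#'   center count.
#' @param tileLength tile-length class.
#' @param ... further colData columns (e.g. `mark`, `replicate`).
#' @return a [TileCounts].
#' @export
tileCountMatrix <- function(centerList, tiles, condition,
                            libSize = NULL, tileLength = 500L, ...) {
  counts <- vapply(centerList, countInTiles, integer(length(tiles)),
                   tiles = tiles)
  if (length(tiles) == 1L) counts <- matrix(counts, nrow = 1L,
                                            dimnames = list(NULL, names(centerList)))
  if (is.null(libSize))
    libSize <- vapply(centerList, function(x) {
      ls <- metadata(x)$libSize
      if (is.null(ls)) length(x) else ls
    }, numeric(1))
  TileCounts(counts, tiles, condition = condition, libSize = libSize,
             tileLength = tileLength, ...)
}

## Mark- and resolution-specific retention thresholds (reads per tile, in at
## least one sample): H3K4me2 50/500bp and 100/1000bp; H3K27me3 30/500bp and
## 60/1000bp. Boundaries are inclusive (>= threshold keeps the tile).
.markThresholds <- list(
  H3K4me2  = c(`500` = 50L, `1000` = 100L),
  H3K27me3 = c(`500` = 30L, `1000` = 60L))

#' Filter tiles by mark-specific count thresholds and input offset
#'
#' A tile is retained when its raw count reaches the mark- and
#' resolution-specific threshold in at least one sample. If input (control)
#' counts are supplied, a tile must additionally exceed its input by at least
#' `inputOffset` reads in at least one ChIP sample; input counts are scaled to
#' each ChIP sample's library size so the comparison is depth-fair.
#'
#' @param counts a [TileCounts] of ChIP samples.
#' @param mark `"H3K4me2"` or `"H3K27me3"` (sets the threshold together with
#'   the tile length), or `threshold` given explicitly.
#' @param inputCounts optional [TileCounts] of matched input samples on the
#'   identical tile set; either one column (shared input) or one per ChIP
#'   sample.
#' @param inputOffset minimum excess of ChIP over scaled input (default 7).
#' @param threshold optional explicit count threshold overriding the mark
#'   table.
#' @return the filtered [TileCounts]; the number of tiles dropped by each
#'   criterion is reported in a message.
#' @export
filterTiles <- function(counts, mark, inputCounts = NULL, inputOffset = 7,
                        threshold = NULL) {
  stopifnot(is(counts, "TileCounts"))
  if (is.null(threshold)) {
    if (!mark %in% names(.markThresholds))
      stop("unknown mark '", mark, "'; expected ",
           paste(names(.markThresholds), collapse = " or "))
    threshold <- .markThresholds[[mark]][[as.character(tileLength(counts))]]
  }
  cnt <- assay(counts, "counts")
  keep <- apply(cnt >= threshold, 1L, any)
  nThresh <- sum(!keep)
  if (!is.null(inputCounts)) {
    stopifnot(is(inputCounts, "TileCounts"))
    if (!identical(rownames(inputCounts), rownames(counts)))
      stop("input counts must cover the identical tile set")
    inp <- assay(inputCounts, "counts")
    if (!ncol(inp) %in% c(1L, ncol(cnt)))
      stop("input must have one column or one per ChIP sample")
    if (ncol(inp) == 1L) inp <- inp[, rep(1L, ncol(cnt)), drop = FALSE]
    inLib <- libSizes(inputCounts)
    if (length(inLib) == 1L) inLib <- rep(inLib, ncol(cnt))
    scaled <- sweep(inp, 2L, libSizes(counts) / inLib, `*`)
    keepInput <- apply(cnt - scaled >= inputOffset, 1L, any)
    nInput <- sum(keep & !keepInput)
    keep <- keep & keepInput
    message(sprintf("filterTiles: %d/%d tiles kept (%d below threshold %d, %d failed input offset %g)",
                    sum(keep), nrow(cnt), nThresh, threshold, nInput,
                    inputOffset))
  } else {
    message(sprintf("filterTiles: %d/%d tiles kept (%d below threshold %d)",
                    sum(keep), nrow(cnt), nThresh, threshold))
  }
  counts[keep, ]
}
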