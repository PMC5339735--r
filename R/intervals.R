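## Interval arithmetic on GRanges. All exported coordinates (ids, BED output)
## are 0-based half-open; in-memory GRanges use the usual 1-based closed
## convention and conversion happens only at I/O boundaries.

#' Merge enriched domains that are less than a gap apart
#'
#' Two domains on the same chromosome are merged when the gap between them
#' (next start minus previous end) is strictly less than `maxGap` base pairs.
#' The result is sorted and non-overlapping; the operation is idempotent.
#'
#' @param domains `GRanges` of domains (strand is ignored).
#' @param maxGap integer gap threshold in bp (default 1000: domains less than
#'   1 kb apart are combined).
#' @return merged, sorted `GRanges`.
#' @examples
#' gr <- GenomicRanges::GRanges("chrS",
#'   IRanges::IRanges(start = c(1, 1201), end = c(500, 1700)))
#' mergeDomains(gr)   # gap 700 < 1000 -> one domain [0,1700)
#' @export
mergeDomains <- function(domains, maxGap = 1000L) {
  stopifnot(is(domains, "GRanges"))
  if (maxGap < 0) stop("'maxGap' must be >= 0")
  ## reduce() merges ranges separated by a gap < min.gapwidth
  GenomicRanges::reduce(BiocGenerics::sort(domains, ignore.strand = TRUE),
                        min.gapwidth = maxGap, ignore.strand = TRUE)
}

#' Partition domains into uniform tiles
#'
#' Each domain is cut from its start into `floor(width / tileLength)` full
#' tiles; any trailing remainder shorter than `tileLength` is dropped, so
#' domains shorter than one tile yield none.
#'
#' @param domains merged (non-overlapping) `GRanges`.
#' @param tileLength tile length in bp, 500 or 1000.
#' @return `GRanges` of tiles, sorted, named by tile id, with a `tile_length`
#'   metadata column.
#' @export
tileDomains <- function(domains, tileLength = 500L) {
  stopifnot(is(domains, "GRanges"))
  tileLength <- as.integer(tileLength)
  if (!tileLength %in% c(500L, 1000L))
    stop("'tileLength' must be 500 or 1000")
  if (!IRanges::isDisjoint(domains, ignore.strand = TRUE))
    stop("domains overlap; run mergeDomains() first")
  domains <- BiocGenerics::sort(domains, ignore.strand = TRUE)
  strand(domains) <- "*"
  keep <- width(domains) >= tileLength
  domains <- domains[keep]
  if (!length(domains)) {
    tiles <- domains
  } else {
    win <- unlist(slidingWindows(domains, width = tileLength,
                                 step = tileLength))
    tiles <- win[width(win) == tileLength]
  }
  mcols(tiles)$tile_length <- rep(tileLength, length(tiles))
  names(tiles) <- tileIds(tiles)
  tiles
}

#' Promoter windows around transcription start sites
#'
#' Promoters are symmetric windows of `flank` bp either side of the TSS: the
#' first transcribed base of the gene on its own strand. Windows are clipped
#' at chromosome bounds when lengths are declared.
#'
#' @param annotation a [GeneAnnotation] (or a stranded `GRanges` of genes).
#' @param flank half-width in bp (default 1000).
#' @return `GRanges` of promoters carrying `gene_id`.
#' @export
promotersFromGenes <- function(annotation, flank = 1000L) {
  g <- if (is(annotation, "GeneAnnotation")) genes(annotation) else annotation
  stopifnot(is(g, "GRanges"))
  if (any(as.character(strand(g)) == "*"))
    stop("genes must be stranded to define a TSS")
  ## flanks may momentarily extend past the chromosome ends; trim() clips
  p <- suppressWarnings(promoters(g, upstream = flank, downstream = flank))
  GenomicRanges::trim(p)
}

#' Introns: gene bodies minus exons
#'
#' @param annotation a [GeneAnnotation].
#' @return `GRanges` of intronic intervals.
#' @export
intronsFromGenes <- function(annotation) {
  stopifnot(is(annotation, "GeneAnnotation"))
  GenomicRanges::setdiff(genes(annotation), exons(annotation),
                         ignore.strand = TRUE)
}

#' Assign each tile to one genomic feature class
#'
#' A tile is labeled by the feature overlapping its midpoint, with fixed
#' precedence promoter > exon > intron > intergenic, so the labels always
#' partition the tile set.
#'
#' @param tiles `GRanges` of tiles.
#' @param annotation a [GeneAnnotation].
#' @param flank promoter half-width passed to [promotersFromGenes()].
#' @return factor of labels (`promoter`, `exon`, `intron`, `intergenic`),
#'   named by tile id.
#' @export
assignFeature <- function(tiles, annotation, flank = 1000L) {
  stopifnot(is(tiles, "GRanges"), is(annotation, "GeneAnnotation"))
  mid <- floor((start(tiles) + end(tiles)) / 2)
  midGr <- GRanges(seqnames(tiles), IRanges(mid, width = 1L))
  lab <- rep("intergenic", length(tiles))
  hit <- function(feat) countOverlaps(midGr, feat, ignore.strand = TRUE) > 0
  if (length(genes(annotation))) {
    lab[hit(intronsFromGenes(annotation))] <- "intron"
    lab[hit(exons(annotation))] <- "exon"
    lab[hit(promotersFromGenes(annotation, flank))] <- "promoter"
  }
  factor(setNames(lab, tileIds(tiles)),
         levels = c("promoter", "exon", "intron", "intergenic"))
}

#' Bivalent tiles: co-occupancy of H3K4me2 and H3K27me3
#'
#' Bivalency is the exact intersection of the tile sets retained (after count
#' filtering) for the active mark H3K4me2 and the repressive mark H3K27me3 in
#' the same tile universe.
#'
#' @param keptK4,keptK27 character vectors of kept tile ids per mark.
#' @param universe optional character vector of all tile ids; if given, both
#'   sets must be subsets of it.
#' @return character vector of bivalent tile ids.
#' @export
detectBivalent <- function(keptK4, keptK27, universe = NULL) {
  if (!is.null(universe)) {
    bad <- setdiff(c(keptK4, keptK27), universe)
    if (length(bad))
      stop("tile ids outside the shared universe: e.g. ", bad[[1]])
  }
  intersect(keptK4, keptK27)
}

#' Distance from each tile to the nearest feature
#'
#' Distance is 0 for overlapping intervals, otherwise the gap in bp between
#' the nearest edges; upstream and downstream are treated symmetrically.
#' Tiles with no feature on their chromosome get `NA`.
#'
#' @param tiles `GRanges` of tiles.
#' @param features `GRanges` of reference features.
#' @return numeric distances named by tile id.
#' @export
distanceToNearestFeature <- function(tiles, features) {
  stopifnot(is(tiles, "GRanges"), is(features, "GRanges"))
  d <- rep(NA_real_, length(tiles))
  if (length(features)) {
    hits <- distanceToNearest(tiles, features, ignore.strand = TRUE)
    d[queryHits(hits)] <- mcols(hits)$distance
  }
  setNames(d, tileIds(tiles))
}

#' Combine significant tiles across the two tiling resolutions
#'
#' Takes the union of significant tiles from the 500 bp and 1,000 bp analyses;
#' wherever a significant 1,000 bp tile overlaps any significant 500 bp tile,
#' only the 500 bp tile(s) are reported.
#'
#' @param res500,res1000 differential-test result data frames (as returned by
#'   [nbGlmLRT()]) with columns `chrom`, `start`, `end` (0-based half-open),
#'   `tileLength` and `class`.
#' @return a data frame of significant tiles (class `up` or `down`).
#' @export
selectSignificantTiles <- function(res500, res1000) {
  sig <- function(res) res[res$class %in% c("up", "down"), , drop = FALSE]
  s5 <- sig(res500); s10 <- sig(res1000)
  if (nrow(s10) && nrow(s5)) {
    gr5 <- GRanges(s5$chrom, IRanges(s5$start + 1L, s5$end))
    gr10 <- GRanges(s10$chrom, IRanges(s10$start + 1L, s10$end))
    drop <- countOverlaps(gr10, gr5, ignore.strand = TRUE) > 0
    s10 <- s10[!drop, , drop = FALSE]
  }
  out <- rbind(s5, s10)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}
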