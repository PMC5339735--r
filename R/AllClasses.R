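#' TileCounts: tile-level read counts with sample metadata
#'
#' A `RangedSummarizedExperiment` holding integer fragment-center counts for a
#' set of uniform genomic tiles (rows) across samples (columns). `colData`
#' carries at least `condition` and `libSize` (the library size recorded at
#' downsampling time, used for CPM normalization); `metadata()$tileLength`
#' records the tile-length class (500 or 1000 bp). Row names are stable tile
#' ids of the form `"chrom:start-end"` in 0-based half-open (BED) coordinates.
#'
#' @slot .Data inherited from `RangedSummarizedExperiment`.
#' @export
setClass("TileCounts", contains = "RangedSummarizedExperiment")

setValidity("TileCounts", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- assay(object, "counts")
    if (any(!is.finite(cnt)) || any(cnt < 0))
      msg <- c(msg, "counts must be finite and non-negative")
  }
  cd <- colData(object)
  if (!all(c("condition", "libSize") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'condition' and 'libSize'")
  else if (any(!is.finite(cd$libSize)) || any(cd$libSize <= 0))
    msg <- c(msg, "library sizes must be positive")
  tl <- metadata(object)$tileLength
  if (is.null(tl) || !tl %in% c(500L, 1000L))
    msg <- c(msg, "metadata()$tileLength must be 500 or 1000")
  if (length(msg)) msg else TRUE
})

#' Construct a TileCounts object
#'
#' @param counts integer matrix, tiles x samples.
#' @param tiles `GRanges` of tile coordinates, one per row of `counts`.
#' @param condition character/factor of per-sample condition labels.
#' @param libSize numeric per-sample library sizes; defaults to column sums.
#' @param tileLength tile-length class, 500 or 1000.
#' @param ... further per-sample columns (e.g. `replicate`, `mark`,
#'   `isInput`) stored in `colData`.
#' @return A [TileCounts] object with tile ids as row names.
#' @examples
#' gr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(c(1, 501), width = 500))
#' m <- matrix(rpois(4, 50), nrow = 2,
#'             dimnames = list(NULL, c("s1", "s2")))
#' tc <- TileCounts(m, gr, condition = c("a", "b"), tileLength = 500)
#' @export
TileCounts <- function(counts, tiles, condition, libSize = colSums(counts),
                       tileLength = 500L, ...) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (length(tiles) != nrow(counts))
    stop("'tiles' must have one range per row of 'counts'")
  cd <- DataFrame(condition = condition, libSize = as.numeric(libSize), ...)
  rownames(counts) <- tileIds(tiles)
  names(tiles) <- rownames(counts)
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowRanges = tiles, colData = cd)
  metadata(se)$tileLength <- as.integer(tileLength)
  new("TileCounts", se)
}

#' @describeIn TileCounts tile-length class (500 or 1000) of a TileCounts.
#' @param x a `TileCounts`.
#' @export
tileLength <- function(x) metadata(x)$tileLength

#' @describeIn TileCounts recorded per-sample library sizes.
#' @export
libSizes <- function(x) setNames(colData(x)$libSize, colnames(x))

setMethod("show", "TileCounts", function(object) {
  cat("TileCounts with", nrow(object), "tiles x", ncol(object), "samples (",
      metadata(object)$tileLength, "bp tiles )\n")
  cat("conditions:",
      paste(unique(as.character(colData(object)$condition)), collapse = ", "),
      "\n")
  callNextMethod()
})

#' MethylationSet: two-channel methylation-array intensities
#'
#' A `SummarizedExperiment` with assays `meth`, `unmeth` (channel intensities)
#' and `detectionP` (per probe x sample detection p-values). `rowData` carries
#' the probe design type (`"I"` or `"II"`), `chrom`, and the blocklist flags
#' `flagPolymorphic`, `flagMultimap`, `flagSexChrom`. `colData` carries
#' `condition` (and usually `replicate`).
#'
#' @export
setClass("MethylationSet", contains = "SummarizedExperiment")

setValidity("MethylationSet", function(object) {
  msg <- character()
  need <- c("meth", "unmeth", "detectionP")
  if (!all(need %in% assayNames(object)))
    msg <- c(msg, paste("assays", paste(need, collapse = ", "), "are required"))
  rd <- rowData(object)
  if (!"type" %in% colnames(rd))
    msg <- c(msg, "rowData must contain probe 'type'")
  else if (!all(rd$type %in% c("I", "II")))
    msg <- c(msg, "probe type must be 'I' or 'II'")
  if (!"condition" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'condition'")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylationSet
#'
#' @param meth,unmeth numeric matrices of methylated / unmethylated channel
#'   intensities (probes x samples).
#' @param detectionP matrix of detection p-values, same shape.
#' @param type probe design type per probe, `"I"` or `"II"`.
#' @param chrom chromosome per probe.
#' @param condition per-sample condition labels.
#' @param flagPolymorphic,flagMultimap,flagSexChrom logical blocklist flags
#'   per probe (default all `FALSE`).
#' @param ... further per-sample columns for `colData`.
#' @return A [MethylationSet].
#' @export
MethylationSet <- function(meth, unmeth, detectionP, type, chrom = "chrS",
                           condition,
                           flagPolymorphic = FALSE, flagMultimap = FALSE,
                           flagSexChrom = FALSE, ...) {
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  detectionP <- as.matrix(detectionP)
  n <- nrow(meth)
  rd <- DataFrame(type = rep_len(type, n), chrom = rep_len(chrom, n),
                  flagPolymorphic = rep_len(flagPolymorphic, n),
                  flagMultimap = rep_len(flagMultimap, n),
                  flagSexChrom = rep_len(flagSexChrom, n))
  cd <- DataFrame(condition = condition, ...)
  se <- SummarizedExperiment(
    assays = list(meth = meth, unmeth = unmeth, detectionP = detectionP),
    rowData = rd, colData = cd)
  new("MethylationSet", se)
}

setMethod("show", "MethylationSet", function(object) {
  rd <- rowData(object)
  cat("MethylationSet with", nrow(object), "probes x", ncol(object),
      "samples\n")
  cat(sprintf("probe types: %d type I, %d type II\n",
              sum(rd$type == "I"), sum(rd$type == "II")))
  callNextMethod()
})

#' GeneAnnotation: a minimal gene model for feature assignment
#'
#' Holds stranded, non-overlapping genes and their exons on a toy genome.
#' Promoters, introns and the intergenic complement are derived on demand by
#' [promotersFromGenes()], [intronsFromGenes()] and [assignFeature()].
#'
#' @slot genes `GRanges` with a `gene_id` metadata column; all stranded.
#' @slot exons `GRanges` with a `gene_id` column; each exon within its gene.
#' @export
setClass("GeneAnnotation",
         representation(genes = "GRanges", exons = "GRanges"))

setValidity("GeneAnnotation", function(object) {
  msg <- character()
  g <- object@genes; e <- object@exons
  if (length(g)) {
    if (is.null(mcols(g)$gene_id)) msg <- c(msg, "genes need a gene_id column")
    if (any(as.character(strand(g)) == "*"))
      msg <- c(msg, "genes must be stranded")
  }
  if (length(e)) {
    if (is.null(mcols(e)$gene_id)) msg <- c(msg, "exons need a gene_id column")
    gid <- match(mcols(e)$gene_id, mcols(g)$gene_id)
    if (any(is.na(gid)))
      msg <- c(msg, "every exon must name a known gene")
    else if (any(start(e) < start(g)[gid] | end(e) > end(g)[gid]))
      msg <- c(msg, "every exon must lie within its parent gene")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneAnnotation constructor.
#' @param genes,exons see slots.
#' @export
GeneAnnotation <- function(genes, exons) new("GeneAnnotation",
                                             genes = genes, exons = exons)

#' @describeIn GeneAnnotation the gene ranges.
#' @param x a `GeneAnnotation`.
#' @export
genes <- function(x) x@genes

#' @describeIn GeneAnnotation the exon ranges.
#' @export
exons <- function(x) x@exons

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation:", length(object@genes), "genes,",
      length(object@exons), "exons on",
      paste(seqlevels(object@genes), collapse = ","), "\n")
})

#' Stable tile/interval identifiers
#'
#' Ids are `"chrom:start-end"` with 0-based half-open coordinates, matching
#' the BED representation the package writes.
#'
#' @param gr a `GRanges`.
#' @return character vector of ids.
#' @export
tileIds <- function(gr) {
  if (!length(gr)) return(character(0))
  paste0(as.character(seqnames(gr)), ":", start(gr) - 1L, "-", end(gr))
}
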