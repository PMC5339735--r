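## Plain-text readers/writers: BED6 (0-based half-open) for reads, domains
## and tiles; a GFF-lite TSV (1-based inclusive, converted on read) for gene
## models; TSV for count matrices, sample sheets and results.

#' Write intervals or read starts as BED6
#'
#' @param gr `GRanges`; width-1 read-start ranges round-trip through
#'   [readBed()].
#' @param path output file.
#' @param names optional name column (default: existing names or `"."`).
#' @export
writeBed <- function(gr, path, names = NULL) {
  if (is.null(names)) names <- names(gr) %||% rep(".", length(gr))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = names, score = 0L,
                   strand = sub("\\*", ".", as.character(strand(gr))))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file into GRanges
#'
#' @param path BED file (0-based half-open).
#' @param seqlengths optional named chromosome lengths.
#' @return `GRanges`.
#' @export
readBed <- function(path, seqlengths = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]),
                strand = if (ncol(df) >= 6) sub("\\.", "*", df[[6]]) else "*")
  if (ncol(df) >= 4 && !all(df[[4]] == ".")) names(gr) <- df[[4]]
  if (!is.null(seqlengths)) seqlengths(gr) <- seqlengths[seqlevels(gr)]
  gr
}

#' Write a gene annotation as GFF-lite TSV
#'
#' Columns: feature (`gene`/`exon`), chrom, start, end (1-based inclusive),
#' strand, gene_id.
#'
#' @param annotation a [GeneAnnotation].
#' @param path output file.
#' @export
writeGffLite <- function(annotation, path) {
  row <- function(gr, feat)
    if (length(gr)) data.frame(feature = feat,
                               chrom = as.character(seqnames(gr)),
                               start = start(gr), end = end(gr),
                               strand = as.character(strand(gr)),
                               gene_id = mcols(gr)$gene_id)
    else NULL
  df <- rbind(row(genes(annotation), "gene"), row(exons(annotation), "exon"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GFF-lite TSV into a GeneAnnotation
#'
#' @param path file written by [writeGffLite()] (1-based inclusive
#'   coordinates).
#' @param seqlengths optional named chromosome lengths.
#' @return a [GeneAnnotation].
#' @export
readGffLite <- function(path, seqlengths = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  mk <- function(feat) {
    d <- df[df$feature == feat, , drop = FALSE]
    gr <- GRanges(d$chrom, IRanges(d$start, d$end), strand = d$strand)
    mcols(gr)$gene_id <- d$gene_id
    if (!is.null(seqlengths)) seqlengths(gr) <- seqlengths[seqlevels(gr)]
    gr
  }
  GeneAnnotation(mk("gene"), mk("exon"))
}

#' Write a TileCounts object as TSV
#'
#' Tile id, coordinates and one count column per sample; library sizes and
#' tile length go into a `#`-prefixed header line.
#'
#' @param tc a [TileCounts].
#' @param path output file.
#' @export
writeCountMatrix <- function(tc, path) {
  rr <- rowRanges(tc)
  df <- data.frame(tileId = rownames(tc),
                   chrom = as.character(seqnames(rr)),
                   start = start(rr) - 1L, end = end(rr),
                   assay(tc, "counts"), check.names = FALSE)
  hdr <- sprintf("#tileLength=%d libSize=%s", tileLength(tc),
                 paste(sprintf("%s:%g", colnames(tc), libSizes(tc)),
                       collapse = ","))
  writeLines(hdr, path)
  suppressWarnings(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE))
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Expected columns: `sampleId`, `path`, `condition`, `replicate`, `mark`,
#' `isInput`, `fragLen`.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
readSampleSheet <- function(path) {
  ss <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sampleId", "path", "condition", "replicate", "mark", "isInput",
            "fragLen")
  miss <- setdiff(need, names(ss))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  ss$isInput <- as.logical(ss$isInput)
  ss
}

#' Write a MethylationSet as an intensity TSV
#'
#' Long-ish wide format: probe, type, chrom, then per sample
#' `meth.<sample>`, `unmeth.<sample>`, `detP.<sample>`, plus the blocklist
#' flag columns.
#'
#' @param ms a [MethylationSet].
#' @param path output file.
#' @export
writeMethylationTsv <- function(ms, path) {
  rd <- rowData(ms)
  df <- data.frame(probe = rownames(ms), type = rd$type, chrom = rd$chrom,
                   flagPolymorphic = rd$flagPolymorphic,
                   flagMultimap = rd$flagMultimap,
                   flagSexChrom = rd$flagSexChrom)
  for (s in colnames(ms)) {
    df[[paste0("meth.", s)]] <- assay(ms, "meth")[, s]
    df[[paste0("unmeth.", s)]] <- assay(ms, "unmeth")[, s]
    df[[paste0("detP.", s)]] <- assay(ms, "detectionP")[, s]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an intensity TSV into a MethylationSet
#'
#' @param path file written by [writeMethylationTsv()].
#' @param condition per-sample condition labels in sample order; when `NULL`,
#'   the text before the last `_repN` suffix of each sample name is used.
#' @return a [MethylationSet].
#' @export
readMethylationTsv <- function(path, condition = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  samples <- sub("^meth\\.", "", grep("^meth\\.", names(df), value = TRUE))
  grab <- function(prefix) {
    m <- as.matrix(df[paste0(prefix, ".", samples)])
    dimnames(m) <- list(df$probe, samples)
    m
  }
  if (is.null(condition)) condition <- sub("_rep[0-9]+$", "", samples)
  MethylationSet(grab("meth"), grab("unmeth"), grab("detP"),
                 type = df$type, chrom = df$chrom, condition = condition,
                 flagPolymorphic = df$flagPolymorphic,
                 flagMultimap = df$flagMultimap,
                 flagSexChrom = df$flagSexChrom)
}
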