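## End-to-end orchestration. Both entry points are plain R functions driven
## by a YAML-serializable config list; every output is a text table under the
## configured output directory, listed with its md5 checksum in a manifest,
## and each stage logs how many units survive it.

#' Default ChIP-seq pipeline configuration
#'
#' The fixed analysis constants (tile lengths, mark-specific count
#' thresholds, the 7-read input offset, the |log2FC| > 0.6 and FDR < 0.05
#' significance rule) with configurable overrides.
#'
#' @param sampleSheet path to the sample-sheet TSV (see [readSampleSheet()]).
#' @param annotation path to a GFF-lite annotation ([writeGffLite()]).
#' @param outDir output directory.
#' @param genomeLength toy chromosome length.
#' @param seed integer seed driving downsampling.
#' @param ... overrides of any default entry.
#' @return named config list.
#' @export
chipseqConfig <- function(sampleSheet, annotation, outDir,
                          genomeLength = 1e6, seed = 1L, ...) {
  cfg <- list(sampleSheet = sampleSheet, annotation = annotation,
              outDir = outDir, genomeLength = genomeLength, seed = seed,
              tileLengths = c(500L, 1000L),
              mergeGap = 1000L, domainWindow = 2000L, domainStep = 500L,
              domainFdr = 0.05, downsampleTarget = NULL,
              inputOffset = 7, fcThresh = 0.6, qThresh = 0.05,
              dispersionMode = "variable",
              promoterFlank = 1000L,
              groupA = "sham", groupB = "ELF",
              dynamicsBaseline = "t0",
              distanceBins = c(0, 1000, 5000, 20000, 1e9))
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

#' Serialize / load a run configuration
#'
#' Configs round-trip through YAML unchanged; [configHash()] gives a stable
#' md5 fingerprint for provenance.
#'
#' @param config a config list.
#' @param path YAML file.
#' @return `readRunConfig()`: the config list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname writeRunConfig
#' @export
configHash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

.openLog <- function(outDir) {
  logPath <- file.path(outDir, "run.log")
  unlink(logPath)
  function(fmt, ...) {
    line <- sprintf(fmt, ...)
    cat(line, "\n", sep = "", file = logPath, append = TRUE)
    message(line)
  }
}

.writeManifest <- function(outDir) {
  files <- setdiff(list.files(outDir, recursive = TRUE),
                   c("manifest.tsv", "run.log"))
  sums <- tools::md5sum(file.path(outDir, files))
  df <- data.frame(file = files, md5 = unname(sums))
  write.table(df, file.path(outDir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  df
}

.writeTsv <- function(df, outDir, name) {
  write.table(df, file.path(outDir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Run the ChIP-seq replicate-variability pipeline
#'
#' Stage order: downsample, fragment centers, per-sample domain calling,
#' union and merge of domains per mark, uniform tiling at 500 and 1,000 bp,
#' tile counting, mark-specific threshold and input-offset filtering, CPM
#' normalization, NB-GLM LRT under both dispersion modes, BH/classification,
#' cross-resolution selection of significant tiles, bivalency detection,
#' CV-squared per condition, variability comparisons (global, by feature, by
#' dynamics, by bivalency), distance trends and a PCA QC. Every table is
#' written to `config$outDir` and checksummed into `manifest.tsv`.
#'
#' @param config list from [chipseqConfig()] (or loaded via
#'   [readRunConfig()]).
#' @return invisibly, a list with the key result tables and the manifest.
#' @export
runChipseqPipeline <- function(config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  log <- .openLog(config$outDir)
  log("config hash %s", configHash(config))
  ss <- readSampleSheet(config$sampleSheet)
  sl <- c(chrS = config$genomeLength)
  ann <- readGffLite(config$annotation, seqlengths = sl)

  reads <- lapply(seq_len(nrow(ss)), function(i)
    readBed(ss$path[i], seqlengths = sl))
  names(reads) <- ss$sampleId
  log("stage read: %d samples, %s reads",
      length(reads), paste(range(lengths(reads)), collapse = "-"))

  target <- config$downsampleTarget %||% min(lengths(reads))
  reads <- lapply(seq_along(reads), function(i)
    downsampleReads(reads[[i]], target, seed = config$seed + 101L * i))
  names(reads) <- ss$sampleId
  log("stage downsample: %d reads per sample", target)

  centers <- lapply(seq_along(reads), function(i)
    fragmentCenters(reads[[i]], fragLen = ss$fragLen[i]))
  names(centers) <- ss$sampleId
  for (i in seq_along(centers)) metadata(centers[[i]])$libSize <- target

  marks <- unique(ss$mark[!ss$isInput])
  results <- list()
  keptIds500 <- list()
  cpm500 <- list()
  filtered500 <- list()
  for (mark in marks) {
    chip <- ss$sampleId[ss$mark == mark & !ss$isInput]
    inputs <- ss$sampleId[ss$mark == mark & ss$isInput]
    doms <- lapply(centers[chip], function(cen)
      callDomains(cen, window = config$domainWindow,
                  step = config$domainStep, fdr = config$domainFdr))
    union <- mergeDomains(do.call(c, unname(doms)), maxGap = config$mergeGap)
    log("stage domains[%s]: %d merged domains (%d-%d per sample)",
        mark, length(union), min(lengths(doms)), max(lengths(doms)))
    writeBed(union, file.path(config$outDir,
                              sprintf("domains_%s.bed", mark)))
    for (tl in config$tileLengths) {
      tiles <- tileDomains(union, tl)
      log("stage tile[%s,%d]: %d tiles", mark, tl, length(tiles))
      tc <- tileCountMatrix(centers[chip], tiles,
                            condition = ss$condition[match(chip, ss$sampleId)],
                            tileLength = tl, mark = mark)
      inTc <- if (length(inputs))
        tileCountMatrix(centers[inputs], tiles,
                        condition = ss$condition[match(inputs, ss$sampleId)],
                        tileLength = tl, mark = mark) else NULL
      kept <- suppressMessages(
        filterTiles(tc, mark, inputCounts = inTc,
                    inputOffset = config$inputOffset))
      log("stage filter[%s,%d]: %d/%d tiles kept", mark, tl,
          nrow(kept), nrow(tc))
      writeCountMatrix(kept, file.path(config$outDir,
                                       sprintf("counts_%s_%d.tsv", mark, tl)))
      cpm <- normalizeCPM(kept)
      grp <- colData(kept)$condition
      sel <- grp %in% c(config$groupA, config$groupB)
      for (mode in c("fixed", "variable")) {
        res <- nbGlmLRT(kept[, sel],
                        factor(grp[sel], levels = c(config$groupA,
                                                    config$groupB)),
                        mode = mode, fcThresh = config$fcThresh,
                        qThresh = config$qThresh)
        results[[sprintf("%s_%d_%s", mark, tl, mode)]] <- res
        log("stage lrt[%s,%d,%s]: %d significant tiles", mark, tl, mode,
            sum(res$class != "no"))
        .writeTsv(res, config$outDir,
                  sprintf("diff_%s_%d_%s.tsv", mark, tl, mode))
      }
      if (tl == 500L) {
        keptIds500[[mark]] <- rownames(kept)
        cpm500[[mark]] <- cpm
        filtered500[[mark]] <- kept
      }
    }
    sel <- selectSignificantTiles(
      results[[sprintf("%s_500_%s", mark, config$dispersionMode)]],
      results[[sprintf("%s_1000_%s", mark, config$dispersionMode)]])
    log("stage select[%s]: %d significant tiles across resolutions",
        mark, nrow(sel))
    .writeTsv(sel, config$outDir, sprintf("significant_%s.tsv", mark))
  }

  bivalent <- if (all(c("H3K4me2", "H3K27me3") %in% marks))
    detectBivalent(keptIds500$H3K4me2, keptIds500$H3K27me3) else character(0)
  log("stage bivalent: %d co-occupied 500 bp tiles", length(bivalent))
  writeLines(bivalent, file.path(config$outDir, "bivalent_tiles.txt"))

  comparisons <- list()
  for (mark in marks) {
    kept <- filtered500[[mark]]
    cpm <- cpm500[[mark]]
    grp <- colData(kept)$condition
    recA <- cv2(cpm, grp, config$groupA)
    recB <- cv2(cpm, grp, config$groupB)
    .writeTsv(recA, config$outDir, sprintf("cv2_%s_%s.tsv", mark,
                                           config$groupA))
    .writeTsv(recB, config$outDir, sprintf("cv2_%s_%s.tsv", mark,
                                           config$groupB))
    feat <- assignFeature(rowRanges(kept), ann, flank = config$promoterFlank)
    biv <- factor(ifelse(rownames(kept) %in% bivalent, "bivalent",
                         paste0(mark, "-only")))
    cmp <- rbind(
      cbind(scope = "global", compareVariability(recA, recB)),
      cbind(scope = "feature", compareVariability(recA, recB, feat)),
      cbind(scope = "bivalency", compareVariability(recA, recB, biv)))
    ## dynamics: differentiation test baseline vs everything else
    if (config$dynamicsBaseline %in% grp) {
      dyn <- nbGlmLRT(kept, factor(ifelse(grp == config$dynamicsBaseline,
                                          "t0", "t5"), c("t0", "t5")),
                      mode = config$dispersionMode,
                      fcThresh = config$fcThresh, qThresh = config$qThresh)
      dc <- dynamicsClasses(dyn, rownames(kept))
      cmp <- rbind(cmp, cbind(scope = "dynamics",
                              compareVariability(recA, recB,
                                                 setNames(dc$dynamics,
                                                          dc$unit))))
      .writeTsv(dyn, config$outDir, sprintf("dynamics_%s.tsv", mark))
    }
    comparisons[[mark]] <- cmp
    .writeTsv(cmp, config$outDir, sprintf("variability_%s.tsv", mark))
    log("stage variability[%s]: %d strata compared", mark, nrow(cmp))

    if (length(bivalent)) {
      bivGr <- rowRanges(kept)[intersect(bivalent, rownames(kept))]
      if (length(bivGr)) {
        dist <- distanceToNearestFeature(rowRanges(kept), bivGr)
        trend <- distanceTrend(setNames(list(recA, recB),
                                        c(config$groupA, config$groupB)),
                               dist, config$distanceBins)
        .writeTsv(trend, config$outDir,
                  sprintf("distance_trend_%s.tsv", mark))
      }
    }
    pca <- pcaQC(cpm)
    .writeTsv(pca, config$outDir, sprintf("pca_%s.tsv", mark))
  }

  manifest <- .writeManifest(config$outDir)
  log("done: %d files in manifest", nrow(manifest))
  invisible(list(results = results, comparisons = comparisons,
                 bivalent = bivalent, manifest = manifest))
}

#' Default methylation pipeline configuration
#'
#' @param intensities path to an intensity TSV ([writeMethylationTsv()]).
#' @param outDir output directory.
#' @param ... overrides.
#' @return named config list.
#' @export
methylationConfig <- function(intensities, outDir, ...) {
  cfg <- list(intensities = intensities, outDir = outDir,
              detectionThresh = 0.05, mOffset = 1,
              fcThresh = 0.6, qThresh = 0.05,
              groupA = "sham", groupB = "ELF", dynamicsBaseline = "t0")
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

#' Run the methylation replicate-variability pipeline
#'
#' Stage order: probe filtering, dasen-style normalization, M-values,
#' moderated t (differentiation: baseline vs rest; exposure: groupA vs
#' groupB), classification, per-condition replicate variance, and
#' variability comparisons (global and by dynamics class). Outputs and a
#' checksum manifest are written to `config$outDir`.
#'
#' @param config list from [methylationConfig()].
#' @return invisibly, a list with the key tables and the manifest.
#' @export
runMethylationPipeline <- function(config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  log <- .openLog(config$outDir)
  log("config hash %s", configHash(config))
  ms <- readMethylationTsv(config$intensities)
  log("stage read: %d probes x %d samples", nrow(ms), ncol(ms))
  ms <- suppressMessages(filterProbes(ms, config$detectionThresh))
  log("stage filter: %d probes kept", nrow(ms))
  ms <- dasenNormalize(ms)
  log("stage dasen: normalized")
  M <- mValues(ms, offset = config$mOffset)
  write.table(data.frame(probe = rownames(M), M, check.names = FALSE),
              file.path(config$outDir, "mvalues.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  grp <- as.character(colData(ms)$condition)

  exposure <- NULL
  sel <- grp %in% c(config$groupA, config$groupB)
  if (sum(sel) >= 4) {
    exposure <- moderatedT(M[, sel],
                           factor(grp[sel], c(config$groupA, config$groupB)),
                           fcThresh = config$fcThresh,
                           qThresh = config$qThresh)
    log("stage moderated-t[exposure]: %d significant CpGs",
        sum(exposure$class != "no"))
    .writeTsv(exposure, config$outDir, "diff_exposure.tsv")
  }
  dynamics <- NULL
  if (config$dynamicsBaseline %in% grp) {
    dynamics <- moderatedT(M, factor(ifelse(grp == config$dynamicsBaseline,
                                            "t0", "t5"), c("t0", "t5")),
                           fcThresh = config$fcThresh,
                           qThresh = config$qThresh)
    log("stage moderated-t[dynamics]: %d hyper, %d hypo CpGs",
        sum(dynamics$class == "hyper"), sum(dynamics$class == "hypo"))
    .writeTsv(dynamics, config$outDir, "diff_dynamics.tsv")
  }

  recs <- list()
  for (cond in unique(grp)) {
    if (sum(grp == cond) < 2) next
    v <- probeVariance(M, grp, cond)
    recs[[cond]] <- data.frame(unit = names(v), variance = v)
    .writeTsv(recs[[cond]], config$outDir,
              sprintf("variance_%s.tsv", cond))
  }
  cmp <- NULL
  if (all(c(config$groupA, config$groupB) %in% names(recs))) {
    cmp <- cbind(scope = "global",
                 compareVariability(recs[[config$groupA]],
                                    recs[[config$groupB]]))
    if (!is.null(dynamics)) {
      dc <- dynamicsClasses(dynamics, rownames(M))
      cmp <- rbind(cmp, cbind(scope = "dynamics",
                              compareVariability(recs[[config$groupA]],
                                                 recs[[config$groupB]],
                                                 setNames(dc$dynamics,
                                                          dc$unit))))
    }
    .writeTsv(cmp, config$outDir, "variability.tsv")
    log("stage variability: %d strata compared", nrow(cmp))
  }
  pca <- pcaQC(M, logTransform = FALSE)
  .writeTsv(pca, config$outDir, "pca.tsv")

  manifest <- .writeManifest(config$outDir)
  log("done: %d files in manifest", nrow(manifest))
  invisible(list(exposure = exposure, dynamics = dynamics,
                 variability = cmp, manifest = manifest))
}

#' Write a bundled synthetic ChIP-seq demo data set
#'
#' Simulates H3K4me2 and H3K27me3 read-start BED files (two conditions plus a
#' t0 baseline, two replicates each, one shared input per mark) over a small
#' toy genome with partially overlapping domain sets (the overlap yields
#' bivalent tiles), writes the sample sheet and GFF-lite annotation, and
#' returns a ready-to-run config.
#'
#' @param dir directory to populate.
#' @param seed integer seed.
#' @param genomeLength toy genome size (default 1 Mb).
#' @param nDomains enriched domains per mark.
#' @param backgroundRate background read density per bp.
#' @param enrichment fold enrichment inside domains.
#' @return config list for [runChipseqPipeline()].
#' @export
demoChipseqData <- function(dir, seed = 1L, genomeLength = 1e6,
                            nDomains = 25L, backgroundRate = 0.012,
                            enrichment = 15) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sl <- c(chrS = genomeLength)
  domainSets <- withSeed(seed, {
    mk <- function() {
      starts <- sort(sample.int(genomeLength - 6000L, nDomains))
      GRanges("chrS", IRanges(starts, width = 2000L +
                                400L * sample.int(8L, nDomains,
                                                  replace = TRUE)),
              seqlengths = sl)
    }
    k4 <- mk()
    ## half of the repressive domains coincide with active ones -> bivalency
    k27 <- mk()
    k27[seq_len(nDomains %/% 2)] <- k4[seq_len(nDomains %/% 2)]
    list(H3K4me2 = GenomicRanges::reduce(k4),
         H3K27me3 = GenomicRanges::reduce(k27))
  })
  ann <- simulateAnnotation(genomeLength = genomeLength, nGenes = 40L,
                            seed = seed + 7L)
  annPath <- file.path(dir, "annotation.tsv")
  writeGffLite(ann, annPath)
  rows <- list()
  i <- 0L
  for (mark in names(domainSets)) {
    for (cond in c("t0", "sham", "ELF")) for (rep in 1:2) {
      i <- i + 1L
      reads <- simulateFragments(domainSets[[mark]], enrichment = enrichment,
                                 backgroundRate = backgroundRate,
                                 genomeLength = genomeLength,
                                 seed = seed + 13L * i)
      p <- file.path(dir, sprintf("%s_%s_rep%d.bed", mark, cond, rep))
      writeBed(reads, p)
      rows[[i]] <- data.frame(sampleId = sprintf("%s_%s_rep%d", mark, cond,
                                                 rep),
                              path = p, condition = cond, replicate = rep,
                              mark = mark, isInput = FALSE, fragLen = 200L)
    }
    i <- i + 1L
    inp <- simulateFragments(GRanges(), enrichment = 1,
                             backgroundRate = backgroundRate,
                             genomeLength = genomeLength,
                             seed = seed + 13L * i)
    p <- file.path(dir, sprintf("%s_input.bed", mark))
    writeBed(inp, p)
    rows[[i]] <- data.frame(sampleId = paste0(mark, "_input"), path = p,
                            condition = "input", replicate = 1L, mark = mark,
                            isInput = TRUE, fragLen = 200L)
  }
  ssPath <- file.path(dir, "samples.tsv")
  write.table(do.call(rbind, rows), ssPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  chipseqConfig(sampleSheet = ssPath, annotation = annPath,
                outDir = file.path(dir, "out"),
                genomeLength = genomeLength, seed = seed)
}

#' Write a bundled synthetic methylation demo data set
#'
#' @param dir directory to populate.
#' @param seed integer seed.
#' @param nProbes probes to simulate.
#' @return config list for [runMethylationPipeline()].
#' @export
demoMethylationData <- function(dir, seed = 1L, nProbes = 2000L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateMethylation(
    nProbes = nProbes, nReplicates = 3L,
    conditions = c("t0", "sham", "ELF"),
    effectConditions = c("sham", "ELF"),
    noiseSd = c(t0 = 0.4, sham = 0.4, ELF = 0.25),
    seed = seed)
  path <- file.path(dir, "intensities.tsv")
  writeMethylationTsv(sim$array, path)
  methylationConfig(intensities = path, outDir = file.path(dir, "out"))
}
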