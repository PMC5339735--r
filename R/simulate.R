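## Seeded generators for every input the pipeline consumes, with ground
## truth recorded. Defaults encode the study conditions the package's tests
## exercise: lognormal tile abundances around 200 reads, edgeR-style NB
## dispersion (variance = mu + phi*mu^2), a single toy chromosome "chrS".

#' Simulate tile counts with known differential and dispersion structure
#'
#' Counts are drawn per condition from NB(mu_c, phi_c) with variance
#' `mu + phi*mu^2`. A fraction of tiles is spiked with a true fold change of
#' `2^effectLog2FC` (half up, half down) in the last condition; a fraction is
#' flagged bivalent, and a per-condition dispersion override for bivalent
#' tiles lets replicate-variability effects be confined to (or spared from)
#' that stratum. Tiles are laid consecutively as `tileLength` windows on
#' "chrS" and annotated with feature classes from a simulated gene model.
#'
#' @param nTiles number of tiles.
#' @param nReplicates replicates per condition.
#' @param conditions condition labels; effects apply to the last one.
#' @param muLogMean,muLogSd log-normal parameters of the per-tile expected
#'   count mu (defaults `log(200)`, 0.5).
#' @param phiByCondition named NB dispersions per condition (>= 0; 0 is
#'   Poisson).
#' @param fracDifferential fraction of tiles with a true fold change.
#' @param effectLog2FC absolute true log2 fold change of spiked tiles.
#' @param fracBivalent fraction of tiles flagged bivalent.
#' @param phiBivalentByCondition optional named dispersions overriding
#'   `phiByCondition` on bivalent tiles.
#' @param tileLength tile width in bp (500 or 1000).
#' @param genomeLength toy chromosome length; default 10 Mb, grown if the
#'   tiles need more room.
#' @param nGenes genes in the simulated annotation used for feature labels.
#' @param seed integer seed; identical seed and parameters give identical
#'   output.
#' @return list with `counts` (a [TileCounts]) and `truth` (data frame per
#'   tile: `tileId`, `class`, true `mu_*` and `phi_*` per condition,
#'   `bivalent`, `feature`).
#' @export
simulateCounts <- function(nTiles = 10000L, nReplicates = 2L,
                           conditions = c("sham", "ELF"),
                           muLogMean = log(200), muLogSd = 0.5,
                           phiByCondition = c(sham = 0.05, ELF = 0.05),
                           fracDifferential = 0, effectLog2FC = 1.5,
                           fracBivalent = 0.2,
                           phiBivalentByCondition = NULL,
                           tileLength = 500L, genomeLength = 1e7,
                           nGenes = 200L, seed = 1L) {
  .assertFraction(fracDifferential, "fracDifferential")
  .assertFraction(fracBivalent, "fracBivalent")
  .assertPositive(exp(muLogMean), "muLogMean")
  .assertPositive(phiByCondition + 1, "phiByCondition")  # finite check
  if (any(phiByCondition < 0)) stop("dispersions must be >= 0")
  if (is.null(names(phiByCondition)) ||
      !all(conditions %in% names(phiByCondition)))
    stop("'phiByCondition' must name every condition")
  genomeLength <- max(genomeLength, nTiles * tileLength)
  withSeed(seed, {
    mu0 <- rlnorm(nTiles, muLogMean, muLogSd)
    cls <- rep("no", nTiles)
    nDiff <- round(fracDifferential * nTiles)
    if (nDiff > 0) {
      idx <- sample.int(nTiles, nDiff)
      up <- idx[seq_len(ceiling(nDiff / 2))]
      cls[idx] <- "down"; cls[up] <- "up"
    }
    bivalent <- rep(FALSE, nTiles)
    nBiv <- round(fracBivalent * nTiles)
    if (nBiv > 0) bivalent[sample.int(nTiles, nBiv)] <- TRUE

    muMat <- matrix(mu0, nTiles, length(conditions),
                    dimnames = list(NULL, conditions))
    last <- conditions[length(conditions)]
    muMat[cls == "up", last] <- muMat[cls == "up", last] * 2^effectLog2FC
    muMat[cls == "down", last] <- muMat[cls == "down", last] * 2^-effectLog2FC
    phiMat <- matrix(rep(phiByCondition[conditions], each = nTiles),
                     nTiles, length(conditions),
                     dimnames = list(NULL, conditions))
    if (!is.null(phiBivalentByCondition)) {
      for (cond in names(phiBivalentByCondition))
        phiMat[bivalent, cond] <- phiBivalentByCondition[[cond]]
    }

    counts <- matrix(0L, nTiles, length(conditions) * nReplicates)
    sampleNames <- character(ncol(counts))
    condCol <- character(ncol(counts))
    j <- 0L
    for (cond in conditions) for (r in seq_len(nReplicates)) {
      j <- j + 1L
      mu <- muMat[, cond]; phi <- phiMat[, cond]
      y <- integer(nTiles)
      pois <- phi < 1e-12
      if (any(pois)) y[pois] <- rpois(sum(pois), mu[pois])
      if (any(!pois)) y[!pois] <- rnbinom(sum(!pois), mu = mu[!pois],
                                          size = 1 / phi[!pois])
      counts[, j] <- y
      sampleNames[j] <- paste0(cond, "_rep", r)
      condCol[j] <- cond
    }
    colnames(counts) <- sampleNames

    starts <- seq(0L, by = tileLength, length.out = nTiles)
    tiles <- GRanges("chrS", IRanges(starts + 1L, width = tileLength),
                     seqlengths = c(chrS = genomeLength))
    mcols(tiles)$tile_length <- as.integer(tileLength)
    ann <- simulateAnnotation(genomeLength = genomeLength, nGenes = nGenes,
                              seed = sample.int(.Machine$integer.max, 1))
    feature <- assignFeature(tiles, ann)

    tc <- TileCounts(counts, tiles,
                     condition = condCol,
                     replicate = as.integer(sub(".*_rep", "", sampleNames)),
                     tileLength = tileLength)
    truth <- data.frame(tileId = tileIds(tiles),
                        class = factor(cls, levels = c("up", "down", "no")),
                        bivalent = bivalent,
                        feature = feature)
    for (cond in conditions) {
      truth[[paste0("mu_", cond)]] <- muMat[, cond]
      truth[[paste0("phi_", cond)]] <- phiMat[, cond]
    }
    rownames(truth) <- truth$tileId
    list(counts = tc, truth = truth)
  })
}

#' Simulate stranded read starts over background plus enriched domains
#'
#' Poisson background positions genome-wide, plus extra positions inside each
#' domain raising its density to `enrichment` times background. Strands are
#' assigned uniformly and read starts are offset from the fragment center by
#' half the fragment length (downstream for `-`, upstream for `+`), so that
#' [fragmentCenters()] recovers the planted centers.
#'
#' @param domains `GRanges` of enriched domains (may be empty; overlaps
#'   allowed).
#' @param enrichment fold enrichment inside domains (> 1).
#' @param backgroundRate background read density per bp (>= 0).
#' @param genomeLength length of the toy chromosome "chrS".
#' @param fragLen mean fragment length in bp.
#' @param seed integer seed.
#' @return width-1 read-start `GRanges` with strand,
#'   `metadata()$fragLen` set, sorted by coordinate.
#' @export
simulateFragments <- function(domains = GRanges(), enrichment = 10,
                              backgroundRate = 0.001, genomeLength = 1e7,
                              fragLen = 200L, seed = 1L) {
  if (backgroundRate < 0) stop("'backgroundRate' must be >= 0")
  if (length(domains) && enrichment <= 1)
    stop("'enrichment' must exceed 1")
  if (length(domains) && any(end(domains) > genomeLength))
    stop("domains must lie within the genome")
  withSeed(seed, {
    nBack <- rpois(1, backgroundRate * genomeLength)
    centers <- if (nBack) sample.int(genomeLength, nBack, replace = TRUE)
               else integer(0)
    for (i in seq_along(domains)) {
      w <- width(domains)[i]
      nExtra <- rpois(1, w * backgroundRate * (enrichment - 1))
      if (nExtra)
        centers <- c(centers,
                     start(domains)[i] + sample.int(w, nExtra,
                                                    replace = TRUE) - 1L)
    }
    n <- length(centers)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    half <- round(fragLen / 2)
    startPos <- ifelse(strand == "+", centers - half, centers + half)
    startPos <- pmin(pmax(startPos, 1L), genomeLength)
    ord <- order(startPos)
    reads <- GRanges("chrS", IRanges(startPos[ord], width = 1L),
                     strand = strand[ord],
                     seqlengths = c(chrS = genomeLength))
    metadata(reads)$fragLen <- fragLen
    reads
  })
}

#' Simulate two-channel methylation-array intensities
#'
#' Per-probe true methylation beta is drawn from a Beta mixture; each
#' sample's M-value is the probe's baseline `log2(beta/(1-beta))` plus
#' Gaussian replicate noise on the M scale, plus `effectDeltaM` for
#' hyper/hypo probes in the effect condition(s). Channel intensities then
#' split a lognormal total intensity according to the sample's methylation
#' level, and type I probes receive an additive background offset on both
#' channels (the design bias the dasen step removes).
#'
#' @param nProbes number of probes.
#' @param nReplicates replicates per condition.
#' @param conditions condition labels.
#' @param effectConditions conditions receiving the hyper/hypo shift
#'   (default: the last condition).
#' @param type2Fraction fraction of type II probes.
#' @param backgroundOffsetType1 additive intensity shift of type I probes.
#' @param betaModes data frame `shape1`, `shape2`, `weight` describing the
#'   Beta mixture of true methylation levels.
#' @param noiseSd replicate noise sd on the M scale; a named vector gives
#'   per-condition noise.
#' @param fracHyper,fracHypo fractions of probes shifted up/down.
#' @param effectDeltaM true |delta M| of shifted probes.
#' @param totalLogMean,totalLogSd lognormal parameters of per-probe total
#'   intensity.
#' @param seed integer seed.
#' @return list with `array` (a [MethylationSet]) and `truth` (per probe:
#'   `probe`, `class`, `trueBeta`).
#' @export
simulateMethylation <- function(nProbes = 10000L, nReplicates = 3L,
                                conditions = c("sham", "ELF"),
                                effectConditions = conditions[length(conditions)],
                                type2Fraction = 0.7,
                                backgroundOffsetType1 = 500,
                                betaModes = data.frame(
                                  shape1 = c(2, 8), shape2 = c(8, 2),
                                  weight = c(0.5, 0.5)),
                                noiseSd = 0.4,
                                fracHyper = 0.05, fracHypo = 0.05,
                                effectDeltaM = 1.5,
                                totalLogMean = log(4000), totalLogSd = 0.25,
                                seed = 1L) {
  .assertFraction(type2Fraction, "type2Fraction")
  .assertFraction(fracHyper, "fracHyper")
  .assertFraction(fracHypo, "fracHypo")
  if (fracHyper + fracHypo > 1) stop("fracHyper + fracHypo must be <= 1")
  if (length(noiseSd) == 1L && is.null(names(noiseSd)))
    noiseSd <- setNames(rep(noiseSd, length(conditions)), conditions)
  if (!all(conditions %in% names(noiseSd)))
    stop("'noiseSd' must be a scalar or name every condition")
  withSeed(seed, {
    comp <- sample.int(nrow(betaModes), nProbes, replace = TRUE,
                       prob = betaModes$weight)
    beta <- rbeta(nProbes, betaModes$shape1[comp], betaModes$shape2[comp])
    beta <- pmin(pmax(beta, 1e-4), 1 - 1e-4)
    total <- rlnorm(nProbes, totalLogMean, totalLogSd)
    type <- ifelse(runif(nProbes) < type2Fraction, "II", "I")
    cls <- rep("no", nProbes)
    nHyper <- round(fracHyper * nProbes)
    nHypo <- round(fracHypo * nProbes)
    idx <- sample.int(nProbes, nHyper + nHypo)
    cls[idx[seq_len(nHyper)]] <- "hyper"
    cls[idx[nHyper + seq_len(nHypo)]] <- "hypo"
    m0 <- log2(beta / (1 - beta))
    shift <- ifelse(cls == "hyper", effectDeltaM,
                    ifelse(cls == "hypo", -effectDeltaM, 0))

    nSamp <- length(conditions) * nReplicates
    meth <- unmeth <- matrix(0, nProbes, nSamp)
    sampleNames <- character(nSamp); condCol <- character(nSamp)
    j <- 0L
    for (cond in conditions) for (r in seq_len(nReplicates)) {
      j <- j + 1L
      m <- m0 + rnorm(nProbes, 0, noiseSd[[cond]])
      if (cond %in% effectConditions) m <- m + shift
      frac <- 2^m / (1 + 2^m)
      meth[, j] <- total * frac
      unmeth[, j] <- total * (1 - frac)
      sampleNames[j] <- paste0(cond, "_rep", r)
      condCol[j] <- cond
    }
    isI <- type == "I"
    meth[isI, ] <- meth[isI, ] + backgroundOffsetType1
    unmeth[isI, ] <- unmeth[isI, ] + backgroundOffsetType1
    detP <- matrix(runif(nProbes * nSamp, 0, 0.04), nProbes, nSamp)
    probeIds <- sprintf("cg%07d", seq_len(nProbes))
    dimnames(meth) <- dimnames(unmeth) <- dimnames(detP) <-
      list(probeIds, sampleNames)
    ms <- MethylationSet(meth, unmeth, detP, type = type,
                         condition = condCol,
                         replicate = as.integer(sub(".*_rep", "", sampleNames)))
    truth <- data.frame(probe = probeIds,
                        class = factor(cls, levels = c("hyper", "hypo", "no")),
                        trueBeta = beta)
    rownames(truth) <- probeIds
    list(array = ms, truth = truth)
  })
}

#' Simulate a toy gene annotation
#'
#' Places non-overlapping genes on both strands of "chrS", each with at least
#' one exon; introns are the within-gene complement of the exons and the
#' intergenic space is everything else, so feature assignment partitions the
#' genome.
#'
#' @param genomeLength chromosome length in bp.
#' @param nGenes number of genes (0 allowed: everything intergenic).
#' @param geneSpan range of gene lengths sampled uniformly.
#' @param seed integer seed.
#' @return a [GeneAnnotation].
#' @export
simulateAnnotation <- function(genomeLength = 1e7, nGenes = 200L,
                               geneSpan = c(2000L, 10000L), seed = 1L) {
  nGenes <- as.integer(nGenes)
  if (nGenes == 0L)
    return(GeneAnnotation(
      GRanges(seqlengths = c(chrS = genomeLength)),
      GRanges(seqlengths = c(chrS = genomeLength))))
  if (nGenes * mean(geneSpan) >= genomeLength)
    stop("cannot pack ", nGenes, " genes into ", genomeLength, " bp")
  withSeed(seed, {
    len <- sample(seq(geneSpan[1], geneSpan[2]), nGenes, replace = TRUE)
    slack <- genomeLength - sum(len)
    gapW <- rexp(nGenes + 1L)
    gaps <- floor(gapW / sum(gapW) * slack)
    starts <- cumsum(gaps[seq_len(nGenes)]) +
      c(0, cumsum(len[-nGenes])) + 1L
    geneStrand <- sample(c("+", "-"), nGenes, replace = TRUE)
    geneIds <- sprintf("gene%04d", seq_len(nGenes))
    genes <- GRanges("chrS", IRanges(starts, width = len),
                     strand = geneStrand,
                     seqlengths = c(chrS = genomeLength))
    mcols(genes)$gene_id <- geneIds
    exonList <- lapply(seq_len(nGenes), function(i) {
      nEx <- sample.int(4L, 1L)
      ## cut the gene at sorted internal breakpoints; odd segments are exons,
      ## so the first segment is always exonic and exons stay within the gene
      bp <- sort(sample.int(len[i] - 1L, 2L * nEx - 1L))
      seg <- cbind(c(1L, bp + 1L), c(bp, len[i]))
      ex <- seg[seq(1L, nrow(seg), by = 2L), , drop = FALSE]
      GRanges("chrS", IRanges(starts[i] + ex[, 1] - 1L,
                              starts[i] + ex[, 2] - 1L),
              strand = geneStrand[i], gene_id = geneIds[i],
              seqlengths = c(chrS = genomeLength))
    })
    exons <- do.call(c, exonList)
    GeneAnnotation(genes, exons)
  })
}
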