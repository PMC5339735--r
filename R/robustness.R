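## Replicate-variability statistics and their condition comparisons.

#' Squared coefficient of variation across replicates
#'
#' CV^2 = (sd / mean)^2 of the normalized (CPM) replicate values of each
#' tile, computed within one condition. Tiles whose replicate mean is zero
#' have no defined CV^2 and are returned as `NA`; their number is recorded in
#' the `nExcluded` attribute.
#'
#' @param norm CPM matrix (from [normalizeCPM()]).
#' @param group per-sample condition labels.
#' @param condition condition whose replicates to use (>= 2 required).
#' @return data frame per tile: `unit`, `n`, `mean`, `sd`, `cv2`; attribute
#'   `nExcluded` counts zero-mean tiles.
#' @export
cv2 <- function(norm, group, condition) {
  cols <- which(as.character(group) == condition)
  if (length(cols) < 2L)
    stop("condition '", condition, "' has fewer than 2 replicates")
  x <- norm[, cols, drop = FALSE]
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (length(cols) - 1L))
  v <- ifelse(m > 0, (s / m)^2, NA_real_)
  out <- data.frame(unit = rownames(norm) %||% as.character(seq_along(m)),
                    n = length(cols), mean = m, sd = s, cv2 = v)
  rownames(out) <- out$unit
  attr(out, "nExcluded") <- sum(m == 0)
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null enumeration when both samples have at most `exactLimit`
#' observations and there are no ties; otherwise the normal approximation
#' with tie-corrected variance and continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param exactLimit largest per-sample size for the exact branch
#'   (default 10).
#' @return two-sided p-value.
#' @export
wilcoxonRankSum <- function(x, y, exactLimit = 10L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= exactLimit && length(y) <= exactLimit
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
}

#' Compare replicate variability between two conditions, by stratum
#'
#' For each stratum (or globally when `strata` is `NULL`), the CV^2 (or
#' variance) distributions of the two conditions are compared by an unpaired
#' two-sided Wilcoxon rank-sum test, with per-side medians, means and counts
#' reported. Units with undefined variability (`NA`) are dropped per side;
#' strata with fewer than 2 usable units on either side are reported with
#' `p = NA` rather than dropped, so stratum accounting stays complete.
#'
#' @param recordsA,recordsB data frames with columns `unit` and `cv2` (as
#'   returned by [cv2()]; a `variance` column is accepted and used when
#'   `cv2` is absent).
#' @param strata optional factor/character of stratum labels named by unit
#'   id (or in `recordsA` order).
#' @return data frame: `stratum`, `nA`, `nB`, `medianA`, `medianB`, `meanA`,
#'   `meanB`, `p`.
#' @export
compareVariability <- function(recordsA, recordsB, strata = NULL) {
  val <- function(r) if ("cv2" %in% names(r)) r$cv2 else r$variance
  a <- setNames(val(recordsA), recordsA$unit)
  b <- setNames(val(recordsB), recordsB$unit)
  if (is.null(strata)) {
    strata <- factor(rep("all", length(a)))
    names(strata) <- names(a)
  } else {
    if (is.null(names(strata))) names(strata) <- recordsA$unit
    strata <- as.factor(strata)
  }
  res <- lapply(levels(strata), function(s) {
    ids <- names(strata)[strata == s]
    xa <- a[intersect(ids, names(a))]; xa <- xa[!is.na(xa)]
    xb <- b[intersect(ids, names(b))]; xb <- xb[!is.na(xb)]
    p <- if (length(xa) < 2L || length(xb) < 2L) NA_real_
         else wilcoxonRankSum(xa, xb)
    stat <- function(fn, x) if (length(x)) unname(fn(x)) else NA_real_
    data.frame(stratum = s, nA = length(xa), nB = length(xb),
               medianA = stat(median, xa), medianB = stat(median, xb),
               meanA = stat(mean, xa), meanB = stat(mean, xb), p = p)
  })
  do.call(rbind, res)
}

#' Differentiation-dynamics class per unit
#'
#' Projects the change classes of a t0-vs-t5 differential test onto an
#' arbitrary unit universe: units present in the results keep their class,
#' absent units are classed as the stable label with `dynamicsMissing =
#' TRUE`.
#'
#' @param diffRes a differential result data frame ([nbGlmLRT()] or
#'   [moderatedT()]) with a `class` column and unit ids as row names.
#' @param units character vector of unit ids to annotate (default: the
#'   results' own units).
#' @return data frame `unit`, `dynamics`, `dynamicsMissing`.
#' @export
dynamicsClasses <- function(diffRes, units = rownames(diffRes)) {
  lev <- levels(diffRes$class)
  idx <- match(units, rownames(diffRes))
  cls <- as.character(diffRes$class)[idx]
  missing <- is.na(idx)
  cls[missing] <- lev[length(lev)]    # stable class ("no")
  data.frame(unit = units, dynamics = factor(cls, levels = lev),
             dynamicsMissing = missing)
}

#' Variability as a function of distance to a feature
#'
#' Bins units by their distance to the nearest feature and summarizes the
#' variability per bin and condition.
#'
#' @param records named list of [cv2()]-style data frames, one per condition.
#' @param distances numeric distances named by unit id
#'   (from [distanceToNearestFeature()]).
#' @param binEdges increasing numeric bin edges covering the observed range.
#' @return data frame: `condition`, `bin`, `n`, `mean`, `median` (empty bins
#'   have `n = 0` and `NA` summaries).
#' @export
distanceTrend <- function(records, distances, binEdges) {
  stopifnot(is.list(records), !is.null(names(records)))
  bins <- levels(cut(numeric(0), binEdges, include.lowest = TRUE))
  res <- lapply(names(records), function(cond) {
    r <- records[[cond]]
    v <- setNames(r$cv2, r$unit)
    d <- distances[names(v)]
    ok <- !is.na(v) & !is.na(d)
    bin <- cut(d[ok], binEdges, include.lowest = TRUE)
    do.call(rbind, lapply(bins, function(b) {
      x <- v[ok][bin == b]
      data.frame(condition = cond, bin = b, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 median = if (length(x)) median(x) else NA_real_)
    }))
  })
  do.call(rbind, res)
}

#' Principal-component QC of normalized counts
#'
#' Samples are projected onto the first two principal components of the
#' column-centered `log2(CPM + 1)` matrix. A thin quality-control view: no
#' inference is attached, and coordinates are defined only up to sign.
#'
#' @param norm CPM matrix (tiles/probes x samples); must have at least as
#'   many rows as samples.
#' @param logTransform set `FALSE` when `norm` is already on a log-like
#'   scale (e.g. M-values).
#' @return data frame `sample`, `PC1`, `PC2` with the fraction of variance
#'   explained in attribute `varExplained`.
#' @export
pcaQC <- function(norm, logTransform = TRUE) {
  if (ncol(norm) < 2L) stop("need >= 2 samples")
  if (nrow(norm) < ncol(norm))
    stop("fewer units than samples; PCA coordinates would be degenerate")
  x <- if (logTransform) log2(norm + 1) else norm
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  out <- data.frame(sample = colnames(norm),
                    PC1 = pc$x[, 1],
                    PC2 = if (k >= 2) pc$x[, 2] else 0)
  attr(out, "varExplained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  out
}
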