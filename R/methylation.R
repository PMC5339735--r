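## Methylation-array arm: probe filtering, dasen-style normalization,
## M-values, empirical-Bayes moderated t, per-probe replicate variance.

#' Filter unreliable probes
#'
#' A probe is removed when its signal is not significantly above background
#' (detection p >= `detectionThresh`) in any sample, or when any blocklist
#' flag is set (known polymorphism, multi-mapping, sex chromosome).
#'
#' @param ms a [MethylationSet].
#' @param detectionThresh detection p-value cutoff (default 0.05; small
#'   detection p means the probe is above background).
#' @return the filtered [MethylationSet]; survivor count reported in a
#'   message.
#' @export
filterProbes <- function(ms, detectionThresh = 0.05) {
  stopifnot(is(ms, "MethylationSet"))
  dp <- assay(ms, "detectionP")
  if (any(is.na(dp))) stop("missing detection p-values")
  rd <- rowData(ms)
  badDetection <- apply(dp >= detectionThresh, 1L, any)
  badFlag <- rd$flagPolymorphic | rd$flagMultimap | rd$flagSexChrom
  keep <- !(badDetection | badFlag)
  message(sprintf("filterProbes: %d/%d probes kept (%d failed detection, %d blocklisted)",
                  sum(keep), nrow(ms), sum(badDetection),
                  sum(badFlag & !badDetection)))
  ms[keep, ]
}

#' dasen-style normalization of two-channel intensities
#'
#' Two steps, applied to the methylated and unmethylated channels
#' independently: (1) background adjustment — per sample, type I intensities
#' are shifted additively so that their 5th percentile matches the type II
#' 5th percentile of the same channel (an approximation to the design-bias
#' correction of the dasen scheme); (2) between-sample quantile
#' normalization, performed separately within each channel x probe-type
#' stratum, after which each stratum's sorted value vector is identical
#' across samples. Ties receive the mean of the reference quantiles they
#' span. The procedure is idempotent up to floating-point noise.
#'
#' @param ms a [MethylationSet] with at least 2 samples.
#' @return normalized [MethylationSet] (detection p-values untouched).
#' @export
dasenNormalize <- function(ms) {
  stopifnot(is(ms, "MethylationSet"))
  if (ncol(ms) < 2L) stop("need >= 2 samples to quantile normalize")
  type <- rowData(ms)$type
  out <- ms
  for (channel in c("meth", "unmeth")) {
    x <- assay(ms, channel)
    isI <- type == "I"
    if (any(isI) && any(!isI)) {
      for (j in seq_len(ncol(x))) {
        shift <- quantile(x[!isI, j], 0.05, names = FALSE) -
          quantile(x[isI, j], 0.05, names = FALSE)
        x[isI, j] <- x[isI, j] + shift
      }
    }
    for (stratum in list(isI, !isI)) {
      if (sum(stratum) < 2L) {
        warning("stratum with < 2 probes skipped in quantile normalization")
        next
      }
      x[stratum, ] <- limma::normalizeQuantiles(x[stratum, , drop = FALSE],
                                                ties = TRUE)
    }
    assays(out)[[channel]] <- x
  }
  out
}

#' M-values from channel intensities
#'
#' `M = log2((meth + offset) / (unmeth + offset))`. Background-adjusted
#' intensities can dip below zero; they are floored at 0 before the offset is
#' added. With `offset = 0` the bare ratio is used, which then requires
#' strictly positive intensities.
#'
#' @param ms a [MethylationSet] (normally after [dasenNormalize()]).
#' @param offset additive regularization alpha (default 1).
#' @return numeric matrix of M-values (probes x samples).
#' @export
mValues <- function(ms, offset = 1) {
  stopifnot(is(ms, "MethylationSet"))
  meth <- pmax(assay(ms, "meth"), 0) + offset
  unmeth <- pmax(assay(ms, "unmeth"), 0) + offset
  if (any(meth <= 0) || any(unmeth <= 0))
    stop("non-positive intensities after offset; increase 'offset'")
  log2(meth / unmeth)
}

#' Empirical-Bayes moderated t-test on M-values
#'
#' Two-group comparison with variance moderation: per-probe residual
#' variances `s^2` (pooled, `d = n1 + n2 - 2` df) are shrunk toward a global
#' prior `s0^2` with prior df `d0`, both obtained by closed-form moment
#' matching of a scaled-F distribution to the observed `s^2`:
#' `s~^2 = (d0*s0^2 + d*s^2) / (d0 + d)`, `t~ = dM / (s~ * sqrt(1/n1+1/n2))`,
#' with p-values from a t distribution on `d + d0` df. `d0 = 0` reproduces
#' the ordinary pooled t; `d0 = Inf` gives a z-like statistic against the
#' prior variance alone.
#'
#' @param M M-value matrix (probes x samples).
#' @param group two-level factor; `dM` is `levels[2]` minus `levels[1]`.
#' @param priorDf force the prior df `d0` (0, `Inf`, or any non-negative
#'   value) instead of estimating it.
#' @param fcThresh,qThresh classification thresholds (effect on the M scale).
#' @return data frame per probe: `dM`, `s2`, `t`, `p`, `q`, `class`
#'   (`hyper`/`hypo`/`no`), with the fitted `d0` and `s02` as attributes
#'   `priorDf` / `priorVar`.
#' @export
moderatedT <- function(M, group, priorDf = NULL, fcThresh = 0.6,
                       qThresh = 0.05) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("moderatedT() compares exactly two groups")
  g1 <- group == levels(group)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  d <- n1 + n2 - 2L
  if (d < 1L) stop("zero residual degrees of freedom")
  m1 <- rowMeans(M[, g1, drop = FALSE])
  m2 <- rowMeans(M[, !g1, drop = FALSE])
  dM <- m2 - m1
  ss <- function(x, m) rowSums((x - m)^2)
  s2 <- (ss(M[, g1, drop = FALSE], m1) + ss(M[, !g1, drop = FALSE], m2)) / d
  if (is.null(priorDf)) {
    prior <- .fitVariancePrior(s2, d)
  } else {
    if (!is.numeric(priorDf) || length(priorDf) != 1L || is.na(priorDf) ||
        priorDf < 0)
      stop("'priorDf' must be a single value >= 0 (Inf allowed)")
    prior <- list(d0 = priorDf,
                  s02 = if (is.infinite(priorDf)) mean(s2) else
                    .fitVariancePrior(s2, d)$s02)
  }
  d0 <- prior$d0; s02 <- prior$s02
  sTilde2 <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  tt <- dM / sqrt(sTilde2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tt), df = d + d0)
  q <- bhAdjust(p)
  out <- data.frame(probe = rownames(M) %||% as.character(seq_along(dM)),
                    dM = dM, s2 = s2, t = tt, p = p, q = q,
                    class = classifyChange(dM, q, fcThresh, qThresh,
                                           labels = c("hyper", "hypo", "no")))
  rownames(out) <- out$probe
  attr(out, "priorDf") <- d0
  attr(out, "priorVar") <- s02
  out
}

## Moment-matching of s^2 ~ s0^2 * F(d, d0): with r = var(s2)/mean(s2)^2,
## r = 2*(d + d0 - 2)/(d*(d0 - 4)), solved for d0; r*d <= 2 means the
## variances scatter no more than a single chi-squared would, so d0 = Inf.
.fitVariancePrior <- function(s2, d) {
  m <- mean(s2)
  v <- var(s2)
  if (m <= 0 || !is.finite(v) || v <= 0) return(list(d0 = Inf, s02 = m))
  r <- v / m^2
  if (r * d <= 2) return(list(d0 = Inf, s02 = m))
  d0 <- (4 * r * d + 2 * d - 4) / (r * d - 2)
  if (d0 <= 4 || !is.finite(d0)) return(list(d0 = Inf, s02 = m))
  list(d0 = d0, s02 = m * (d0 - 2) / d0)
}

#' Per-probe replicate variance of M-values
#'
#' Unbiased sample variance (divisor n-1) across the replicates of one
#' condition.
#'
#' @param M M-value matrix.
#' @param group per-sample condition labels.
#' @param condition which condition to summarize.
#' @return numeric variances named by probe.
#' @export
probeVariance <- function(M, group, condition) {
  cols <- which(as.character(group) == condition)
  if (length(cols) < 2L)
    stop("condition '", condition, "' has fewer than 2 replicates")
  x <- M[, cols, drop = FALSE]
  m <- rowMeans(x)
  setNames(rowSums((x - m)^2) / (length(cols) - 1L),
           rownames(M) %||% as.character(seq_len(nrow(M))))
}
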