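## Independent brute-force oracles used to pin expected values. These stay
## deliberately naive (per-base-pair scans, O(n^2) loops, exhaustive
## enumeration, grid maximization) and share no code with the implementation
## paths they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

## pairwise gap-closure merge: repeatedly fuse any two intervals on the same
## chrom whose gap is < maxGap, until stable
bruteMerge <- function(df, maxGap = 1000) {
  repeat {
    merged <- FALSE
    i <- 1
    while (i <= nrow(df)) {
      j <- i + 1
      while (j <= nrow(df)) {
        if (df$chrom[i] == df$chrom[j]) {
          gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j])
          if (gap < maxGap) {   # negative gap = overlap
            df$start[i] <- min(df$start[i], df$start[j])
            df$end[i] <- max(df$end[i], df$end[j])
            df <- df[-j, , drop = FALSE]
            merged <- TRUE
            next
          }
        }
        j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  df[order(df$chrom, df$start), , drop = FALSE]
}

## min over all features of the edge gap (0 when overlapping), 0-based spans
bruteDistance <- function(tileStart, tileEnd, featStarts, featEnds) {
  d <- Inf
  for (k in seq_along(featStarts)) {
    if (tileStart < featEnds[k] && featStarts[k] < tileEnd) d <- min(d, 0)
    else if (tileEnd <= featStarts[k]) d <- min(d, featStarts[k] - tileEnd)
    else d <- min(d, tileStart - featEnds[k])
  }
  d
}

## double loop over centers and tiles (0-based half-open positions)
bruteCount <- function(centers0, tileStarts0, tileEnds0) {
  out <- integer(length(tileStarts0))
  for (c in centers0)
    for (t in seq_along(out))
      if (c >= tileStarts0[t] && c < tileEnds0[t])
        out[t] <- out[t] + 1L
  out
}

## BH step-up from its definition: q_(i) = min_{j >= i} m * p_(j) / j
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

## exact two-sided Wilcoxon p by enumeration of every assignment of the
## pooled ranks to the x-sample; two-sided rule: 2 * min(tail) capped at 1
bruteWilcoxNull <- function(nx, ny) {
  n <- nx + ny
  combs <- combn(n, nx)
  apply(combs, 2, sum) - nx * (nx + 1) / 2  # Mann-Whitney U per assignment
}

bruteWilcoxP <- function(u, nullU) {
  lo <- mean(nullU <= u)
  hi <- mean(nullU >= u)
  min(1, 2 * min(lo, hi))
}

## brute-force NB log-likelihood maximization over the mean coefficient at a
## FIXED dispersion, by iterated grid refinement (independent of the Fisher
## scoring path). Offsets f scale the mean per sample.
bruteNBMeanLL <- function(y, f, phi, rounds = 4, width = 3) {
  center <- max(sum(y) / sum(f), 1e-3)
  lo <- log(center) - width
  hi <- log(center) + width
  ll <- function(b) {
    mu <- pmax(b * f, 1e-300)
    if (phi < 1e-10) sum(dpois(y, mu, log = TRUE))
    else sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
  for (r in seq_len(rounds)) {
    grid <- seq(lo, hi, length.out = 200)
    vals <- vapply(grid, function(g) ll(exp(g)), numeric(1))
    k <- which.max(vals)
    step <- grid[2] - grid[1]
    lo <- grid[max(1, k - 1)]
    hi <- grid[min(length(grid), k + 1)]
  }
  max(vals)
}

## LRT at fixed dispersion via the grid maximizer
bruteLRT <- function(y, f, group, phi) {
  l1 <- sum(vapply(levels(group), function(g) {
    i <- group == g
    bruteNBMeanLL(y[i], f[i], phi)
  }, numeric(1)))
  l0 <- bruteNBMeanLL(y, f, phi)
  max(0, 2 * (l1 - l0))
}

## Jaccard of the called interval best overlapping the truth
bestJaccard <- function(called, truth) {
  if (!length(called)) return(0)
  ov <- called[countOverlaps(called, truth) > 0]
  if (!length(ov)) return(0)
  max(vapply(seq_along(ov), function(i) {
    sum(width(GenomicRanges::intersect(ov[i], truth))) /
      sum(width(GenomicRanges::union(ov[i], truth)))
  }, numeric(1)))
}

conditionOf <- function(tc) as.character(colData(tc)$condition)
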