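## Read starts -> centers -> domains -> tile counts -> threshold filtering.

mkReads <- function(starts0, strands, fragLen = 200, genomeLength = 1e6) {
  r <- GRanges("chrS", IRanges(starts0 + 1L, width = 1L), strand = strands,
               seqlengths = c(chrS = genomeLength))
  S4Vectors::metadata(r)$fragLen <- fragLen
  r
}

test_that("fragment centers shift read 5' ends by half the fragment length", {
  r <- mkReads(c(1000, 1000), c("+", "-"), fragLen = 200)
  cen <- fragmentCenters(r)
  expect_setequal(start(cen) - 1L, c(1100L, 900L))
  expect_error(fragmentCenters(r, fragLen = 0), "positive")
  runstranded <- GRanges("chrS", IRanges(10, width = 1), strand = "*")
  expect_error(fragmentCenters(runstranded, fragLen = 200), "strand")
  ## clipping at chromosome bounds
  edge <- fragmentCenters(mkReads(c(10, 999990), c("-", "+"), 200))
  expect_true(all(start(edge) >= 1 & end(edge) <= 1e6))
})

test_that("downsampling retains exactly the target, deterministically", {
  r <- mkReads(sample.int(1e5, 100), sample(c("+", "-"), 100, TRUE))
  d1 <- downsampleReads(r, 50, seed = 9)
  d2 <- downsampleReads(r, 50, seed = 9)
  expect_length(d1, 50L)
  expect_identical(start(d1), start(d2))
  expect_false(is.unsorted(start(d1)))
  expect_equal(S4Vectors::metadata(d1)$libSize, 50L)
  ## identity at full depth (up to ordering)
  expect_setequal(start(downsampleReads(r, length(r), seed = 1)), start(r))
  expect_error(downsampleReads(r, length(r) + 1, seed = 1), "exceeds")
})

test_that("domain caller recovers a planted enriched region and stays quiet on null data", {
  truth <- GRanges("chrS", IRanges(10001, 15000))
  reads <- simulateFragments(truth, enrichment = 10, backgroundRate = 0.002,
                             genomeLength = 1e7, seed = 31)
  cen <- fragmentCenters(reads)
  called <- callDomains(cen, window = 1000, step = 250)
  expect_gte(bestJaccard(called, truth), 0.8)

  ## center-density round trip: enrichment recovered inside the domain
  inside <- sum(countOverlaps(cen, truth))
  dIn <- inside / sum(width(truth))
  dOut <- (length(cen) - inside) / (1e7 - sum(width(truth)))
  expect_equal(dIn / dOut, 10, tolerance = 0.15)

  nullReads <- simulateFragments(GRanges(), enrichment = 1,
                                 backgroundRate = 5e-4, genomeLength = 1e7,
                                 seed = 32)
  expect_length(callDomains(fragmentCenters(nullReads)), 0L)

  ## scale property: doubling counts by pooling two seeds leaves the
  ## detected region intact (the rate-ratio test is relative)
  expect_length(callDomains(fragmentCenters(nullReads), window = 4000), 0L)
})

test_that("tile counting respects half-open boundaries and matches a double loop", {
  tiles <- tileDomains(GRanges("chrS", IRanges(1, 2000)), 500)
  cen <- GRanges("chrS", IRanges(c(499, 500) + 1L, width = 1L))
  cnt <- countInTiles(cen, tiles)
  expect_equal(unname(cnt[1:2]), c(1L, 1L))

  set.seed(3)
  centers0 <- sample(0:9999, 800, replace = TRUE)
  cgr <- GRanges("chrS", IRanges(centers0 + 1L, width = 1L))
  tstart <- seq(0, 9500, by = 500)
  tgr <- GRanges("chrS", IRanges(tstart + 1L, width = 500L))
  got <- countInTiles(cgr, tgr)
  expect_equal(unname(got), bruteCount(centers0, tstart, tstart + 500))
  expect_lte(sum(got), length(cgr))
})

mkCounts <- function(mat, tileLength = 500L, lib = NULL) {
  n <- nrow(mat)
  tiles <- GRanges("chrS", IRanges(seq(1, by = tileLength, length.out = n),
                                   width = tileLength))
  TileCounts(mat, tiles, condition = rep("c", ncol(mat)),
             libSize = lib %||% rep(1e6, ncol(mat)), tileLength = tileLength)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("count thresholds are mark- and resolution-specific, boundary inclusive", {
  m <- rbind(c(49, 49, 49), c(50, 0, 0))
  tc <- mkCounts(m)
  kept <- suppressMessages(filterTiles(tc, "H3K4me2"))
  expect_equal(nrow(kept), 1L)
  expect_equal(unname(assay(kept, "counts")[1, 1]), 50L)

  m2 <- rbind(c(59, 59), c(60, 12))
  tc2 <- mkCounts(m2, tileLength = 1000L)
  kept2 <- suppressMessages(filterTiles(tc2, "H3K27me3"))
  expect_equal(nrow(kept2), 1L)

  expect_error(suppressMessages(filterTiles(tc, "H3K9me3")), "unknown mark")
})

test_that("the input-offset criterion requires >= 7 reads above depth-scaled input", {
  ## boundary of the input rule in isolation (explicit count threshold 40):
  ## ChIP 40 over input 34 is a 6-read excess and fails; 41 passes
  chip <- mkCounts(rbind(c(40, 40), c(41, 10), c(300, 5)))
  inp <- mkCounts(rbind(c(34, 34), c(34, 34), c(5, 5)))
  kept <- suppressMessages(
    filterTiles(chip, threshold = 40, inputCounts = inp))
  expect_setequal(rownames(kept), rownames(chip)[2:3])

  ## combined with the mark threshold: 54 >= 50 reads but only 6 above input
  chipM <- mkCounts(rbind(c(54, 54), c(55, 10), c(300, 5)))
  inpM <- mkCounts(rbind(c(48, 48), c(48, 48), c(5, 5)))
  keptM <- suppressMessages(
    filterTiles(chipM, "H3K4me2", inputCounts = inpM))
  expect_setequal(rownames(keptM), rownames(chipM)[2:3])

  ## input scaled to ChIP depth: half-depth input counts double before
  ## comparison, so 40 - 2*17 = 6 fails but 40 - 2*16 = 8 passes
  inpHalf <- mkCounts(rbind(c(17, 17), c(16, 16), c(0, 0)),
                      lib = rep(5e5, 2))
  chip2 <- mkCounts(rbind(c(40, 40), c(40, 40), c(50, 50)))
  kept2 <- suppressMessages(
    filterTiles(chip2, threshold = 30, inputCounts = inpHalf))
  expect_setequal(rownames(kept2), rownames(chip2)[2:3])
})

test_that("filtering is monotone: adding counts never removes a kept tile", {
  set.seed(5)
  base <- matrix(rpois(300, 40), ncol = 3)
  extra <- base + matrix(rpois(300, 15), ncol = 3)
  k1 <- rownames(suppressMessages(filterTiles(mkCounts(base), "H3K4me2")))
  k2 <- rownames(suppressMessages(filterTiles(mkCounts(extra), "H3K4me2")))
  expect_true(all(k1 %in% k2))
})
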