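## Interval arithmetic: merging, tiling, promoters, feature assignment,
## bivalency, distances and the cross-resolution selection rule.

gr0 <- function(starts0, ends0, chrom = "chrS", strand = "*", ...) {
  GRanges(chrom, IRanges(starts0 + 1L, ends0), strand = strand, ...)
}

test_that("domains merge iff the gap is strictly below the threshold", {
  m <- mergeDomains(gr0(c(0, 1200), c(500, 1700)))     # gap 700
  expect_equal(start(m) - 1L, 0L)
  expect_equal(end(m), 1700L)

  m2 <- mergeDomains(gr0(c(0, 1500), c(500, 2000)))    # gap exactly 1000
  expect_length(m2, 2L)

  m3 <- mergeDomains(gr0(c(0, 1499), c(500, 2000)))    # gap 999
  expect_length(m3, 1L)

  ## idempotence
  expect_identical(mergeDomains(m3), m3)
})

test_that("merging agrees with a brute-force pairwise oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(3:60, 1)
    starts <- sample.int(50000, n)
    lens <- sample.int(3000, n)
    chrom <- sample(c("chrA", "chrB"), n, replace = TRUE)
    df <- data.frame(chrom = chrom, start = starts, end = starts + lens)
    got <- mergeDomains(GRanges(df$chrom, IRanges(df$start + 1L, df$end)))
    gdf <- data.frame(chrom = as.character(seqnames(got)),
                      start = start(got) - 1L, end = end(got))
    gdf <- gdf[order(gdf$chrom, gdf$start), ]
    exp <- bruteMerge(df)
    expect_equal(gdf$chrom, exp$chrom)
    expect_equal(gdf$start, exp$start)
    expect_equal(gdf$end, exp$end)
  }
})

test_that("tiling partitions domains into full-length tiles, dropping remainders", {
  t1 <- tileDomains(gr0(0, 1700), 500)
  expect_equal(start(t1) - 1L, c(0L, 500L, 1000L))
  expect_equal(width(t1), rep(500L, 3))

  expect_length(tileDomains(gr0(0, 499), 500), 0L)

  ## conservation: total tiled bases = sum floor(len/L)*L
  set.seed(7)
  starts <- cumsum(sample(3000:9000, 20))
  lens <- sample(200:4200, 20)
  dom <- mergeDomains(gr0(starts, starts + lens))
  tl <- tileDomains(dom, 1000)
  expect_equal(sum(width(tl)), sum(floor(width(dom) / 1000) * 1000))

  ## merge -> tile is idempotent in the tile set
  expect_identical(tileDomains(mergeDomains(dom), 1000), tl)

  ## unmerged overlapping input is rejected
  expect_error(tileDomains(gr0(c(0, 100), c(1000, 1200)), 500), "overlap")
})

test_that("promoters are strand-aware TSS flanks, clipped at bounds", {
  gplus <- gr0(5000, 9000, strand = "+", gene_id = "g1")
  p <- promotersFromGenes(gplus, flank = 1000)
  expect_equal(start(p) - 1L, 4000L)
  expect_equal(end(p), 6000L)

  gminus <- gr0(5000, 9000, strand = "-", gene_id = "g2")
  pm <- promotersFromGenes(gminus, flank = 1000)
  ## centered on the 0-based TSS position 8999
  expect_equal(start(pm) - 1L, 8000L)
  expect_equal(end(pm), 10000L)

  gedge <- GRanges("chrS", IRanges(201, 800), strand = "+",
                   seqlengths = c(chrS = 100000))
  pe <- promotersFromGenes(gedge, flank = 1000)
  expect_equal(start(pe) - 1L, 0L)
  expect_equal(end(pe), 1200L)

  expect_error(promotersFromGenes(gr0(0, 100, strand = "*")), "strand")
})

test_that("feature assignment partitions tiles with promoter precedence", {
  genes <- gr0(c(10000, 30000), c(20000, 40000), strand = c("+", "-"),
               gene_id = c("g1", "g2"))
  exons <- gr0(c(10000, 15000, 30000), c(12000, 16000, 33000),
               strand = c("+", "+", "-"), gene_id = c("g1", "g1", "g2"))
  ann <- GeneAnnotation(genes, exons)
  tiles <- tileDomains(gr0(9000, 46000), 500)
  lab <- assignFeature(tiles, ann)
  expect_length(lab, length(tiles))
  expect_false(any(is.na(lab)))
  expect_equal(sum(table(lab)), length(tiles))
  ## midpoint in promoter overlapping exon 1 -> promoter wins
  expect_equal(as.character(lab[["chrS:10000-10500"]]), "promoter")
  ## far outside genes
  expect_equal(as.character(lab[["chrS:45000-45500"]]), "intergenic")
  ## inside gene 1 beyond exon 2, outside promoter
  expect_equal(as.character(lab[["chrS:17000-17500"]]), "intron")
})

test_that("bivalency is the exact intersection of kept tile sets", {
  expect_identical(detectBivalent(c("a", "b"), c("c")), character(0))
  expect_setequal(detectBivalent(c("a", "b"), c("b", "a")), c("a", "b"))
  k4 <- sprintf("t%d", 1:30); k27 <- sprintf("t%d", 20:40)
  expect_lte(length(detectBivalent(k4, k27)), min(length(k4), length(k27)))
  expect_error(detectBivalent("a", "zzz", universe = c("a", "b")), "universe")
})

test_that("distance to nearest feature matches the brute-force minimum", {
  tiles <- gr0(c(100, 100), c(600, 600))[1]
  expect_equal(unname(distanceToNearestFeature(tiles, gr0(550, 900))), 0)
  expect_equal(unname(distanceToNearestFeature(tiles, gr0(800, 900))), 200)

  set.seed(11)
  nf <- 300
  fs <- sample.int(90000, nf); fe <- fs + sample.int(2000, nf)
  feats <- gr0(fs, fe)
  tileS <- seq(0, 95000, by = 500)
  tl <- gr0(tileS, tileS + 500)
  got <- distanceToNearestFeature(tl, feats)
  for (i in seq(1, length(tl), by = 13))
    expect_equal(unname(got[i]),
                 bruteDistance(tileS[i], tileS[i] + 500, fs, fe))

  ## no feature on the chromosome -> NA sentinel
  other <- GRanges("chrZ", IRanges(1, 10))
  suppressWarnings(
    expect_true(is.na(distanceToNearestFeature(tl, other)[1])))
})

test_that("significant 500 bp tiles shadow overlapping significant 1 kb tiles", {
  mk <- function(starts, lens, cls) {
    data.frame(chrom = "chrS", start = starts, end = starts + lens,
               tileLength = lens, tileId = sprintf("chrS:%d-%d", starts,
                                                   starts + lens),
               class = factor(cls, levels = c("up", "down", "no")))
  }
  r500 <- mk(c(0, 2000), 500, c("up", "no"))
  r1000 <- mk(c(0, 5000), 1000, c("down", "up"))
  sel <- selectSignificantTiles(r500, r1000)
  ## the 1 kb tile at 0 overlaps the significant 500 bp tile -> dropped
  expect_setequal(sel$tileId, c("chrS:0-500", "chrS:5000-6000"))

  ## no significant tiles anywhere -> empty
  expect_equal(nrow(selectSignificantTiles(mk(0, 500, "no"),
                                           mk(0, 1000, "no"))), 0L)
})
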