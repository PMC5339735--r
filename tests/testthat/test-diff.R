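## Differential testing: CPM, dispersion estimation, NB-GLM LRT, BH,
## classification.

simCounts <- function(...) simulateCounts(...)
grpOf <- function(tc, levels) factor(conditionOf(tc), levels)

test_that("CPM normalization is exact and inverts library-size scaling", {
  m <- matrix(c(100L, 100L), 1)
  expect_equal(unname(normalizeCPM(m, libSize = c(1e6, 2e6))),
               matrix(c(100, 50), 1))
  expect_error(normalizeCPM(m, libSize = c(0, 1)), "positive")
})

test_that("Poisson data yield near-zero dispersion estimates", {
  set.seed(2)
  y <- matrix(rpois(2000 * 4, 100), 2000)
  phi <- estimateDispersion(y, factor(rep(c("a", "b"), each = 2)),
                            mode = "fixed", libSize = rep(1e6, 4))
  expect_lt(mean(phi), 0.005)
  ## an exactly variance = mean tile (moderation aside, grid floor applies)
  expect_lt(median(phi), 0.002)
})

test_that("dispersion recovery at NB(mu=200, phi=0.1) with 4 replicates", {
  sim <- simCounts(nTiles = 3000, nReplicates = 4,
                   phiByCondition = c(sham = 0.1, ELF = 0.1), seed = 41)
  phi <- estimateDispersion(sim$counts, grpOf(sim$counts, c("sham", "ELF")),
                            mode = "fixed")
  expect_gt(mean(phi, na.rm = TRUE), 0.07)
  expect_lt(mean(phi, na.rm = TRUE), 0.13)
})

test_that("variable mode preserves the dispersion ordering between groups", {
  sim <- simCounts(nTiles = 2000, nReplicates = 3,
                   phiByCondition = c(sham = 0.05, ELF = 0.2), seed = 42)
  phi <- estimateDispersion(sim$counts, grpOf(sim$counts, c("sham", "ELF")),
                            mode = "variable")
  expect_gt(mean(phi[, "phi_ELF"] > phi[, "phi_sham"], na.rm = TRUE), 0.95)
})

test_that("identical groups give LRT 0 and relabeling flips the fold change", {
  y <- matrix(rep(c(120L, 80L, 100L), 2), nrow = 1)
  g <- factor(c("a", "b", "a", "b", "a", "b"), c("a", "b"))
  ## identical counts per group pattern: build counts equal across groups
  y2 <- matrix(c(100L, 110L, 90L, 100L, 110L, 90L), nrow = 1)
  g2 <- factor(rep(c("a", "b"), each = 3), c("a", "b"))
  y2 <- matrix(c(100L, 110L, 90L, 100L, 110L, 90L), nrow = 1)
  res <- nbGlmLRT(y2, g2, mode = "fixed", libSize = rep(1e6, 6))
  expect_equal(res$LRT, 0, tolerance = 1e-6)
  expect_equal(res$p, 1, tolerance = 1e-6)

  set.seed(9)
  y3 <- matrix(rnbinom(40 * 6, mu = 150, size = 10), 40)
  g3 <- factor(rep(c("a", "b"), each = 3), c("a", "b"))
  r1 <- nbGlmLRT(y3, g3, mode = "fixed", libSize = rep(1e6, 6))
  r2 <- nbGlmLRT(y3, factor(g3, c("b", "a")), mode = "fixed",
                 libSize = rep(1e6, 6))
  expect_equal(r1$LRT, r2$LRT, tolerance = 1e-6)
  expect_equal(r1$log2FC, -r2$log2FC, tolerance = 1e-10)
})

test_that("LRT at a given dispersion matches brute-force grid maximization", {
  set.seed(13)
  g <- factor(rep(c("a", "b"), each = 3), c("a", "b"))
  f <- rep(1, 6)
  for (k in 1:8) {
    y <- matrix(c(rnbinom(3, mu = 100, size = 20), rnbinom(3, mu = 400,
                                                           size = 20)), 1)
    phi <- 0.05
    res <- nbGlmLRT(y, g, mode = "fixed", dispersion = phi,
                    libSize = rep(1e6, 6))
    expect_equal(res$LRT, bruteLRT(y[1, ], f, g, phi), tolerance = 1e-3)
  }
  ## all-zero tile is flagged, not tested
  yz <- rbind(rep(0L, 6), matrix(rpois(6, 50), 1))
  rz <- nbGlmLRT(yz, g, mode = "fixed", libSize = rep(1e6, 6))
  expect_true(is.na(rz$p[1]))
  expect_equal(as.character(rz$class[1]), "no")
})

test_that("fixed-mode dispersion estimates maximize the moderated CR objective on the grid", {
  ## independent re-computation of the Cox-Reid adjusted profile likelihood
  ## at the estimate vs at perturbed dispersions
  set.seed(21)
  y <- matrix(rnbinom(30 * 6, mu = 200, size = 1 / 0.1), 30)
  g <- factor(rep(c("a", "b"), each = 3), c("a", "b"))
  f <- rep(1, 6)
  phi <- estimateDispersion(y, g, mode = "fixed", priorDf = 0,
                            libSize = rep(1e6, 6))
  apl <- function(yy, ph) {
    tot <- 0
    for (gg in levels(g)) {
      i <- g == gg
      opt <- optimize(function(lb) {
        mu <- exp(lb) * f[i]
        -sum(dnbinom(yy[i], size = 1 / ph, mu = mu, log = TRUE))
      }, c(0, 12))
      mu <- exp(opt$minimum) * f[i]
      tot <- tot - opt$objective - 0.5 * log(sum(mu / (1 + ph * mu)))
    }
    tot
  }
  for (i in seq(1, 30, by = 4)) {
    if (phi[i] <= 0) next
    a0 <- apl(y[i, ], phi[i])
    expect_gte(a0, apl(y[i, ], phi[i] * 1.6) - 1e-6)
    expect_gte(a0, apl(y[i, ], phi[i] / 1.6) - 1e-6)
  }
})

test_that("BH adjustment equals the step-up definition and handles NA", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  p <- c(0.01, NA, 0.5)
  q <- bhAdjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bruteBH(p[c(1, 3)]))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  ## monotone in sorted p
  set.seed(1)
  ps <- sort(runif(50))
  expect_false(is.unsorted(bhAdjust(ps)))
})

test_that("change classification applies strict FDR and fold-change cuts", {
  expect_equal(as.character(classifyChange(0.7, 0.01)), "up")
  expect_equal(as.character(classifyChange(0.7, 0.2)), "no")
  expect_equal(as.character(classifyChange(-0.61, 0.049)), "down")
  expect_equal(as.character(classifyChange(0.6, 0.01)), "no")   # boundary
  expect_equal(as.character(classifyChange(0.8, 0.05)), "no")   # boundary
  expect_equal(as.character(classifyChange(NA, NA)), "no")
})

test_that("variable mode does not out-call fixed mode under heterogeneous dispersion", {
  sim <- simCounts(nTiles = 1500, nReplicates = 3,
                   phiByCondition = c(sham = 0.02, ELF = 0.3),
                   fracDifferential = 0, seed = 8)
  g <- grpOf(sim$counts, c("sham", "ELF"))
  rf <- nbGlmLRT(sim$counts, g, mode = "fixed")
  rv <- nbGlmLRT(sim$counts, g, mode = "variable")
  expect_lte(sum(rv$class != "no"), sum(rf$class != "no"))
  expect_lte(sum(rv$p < 0.05, na.rm = TRUE), sum(rf$p < 0.05, na.rm = TRUE))
})

test_that("fixed-mode results track an independent count-GLM implementation", {
  sim <- simulateCounts(nTiles = 400, nReplicates = 3,
                        phiByCondition = c(sham = 0.08, ELF = 0.08),
                        fracDifferential = 0.1, seed = 77)
  cnt <- assay(sim$counts, "counts")
  g <- factor(conditionOf(sim$counts), c("sham", "ELF"))
  mine <- nbGlmLRT(sim$counts, g, mode = "fixed")
  dge <- edgeR::DGEList(counts = cnt, group = g,
                        lib.size = libSizes(sim$counts))
  design <- stats::model.matrix(~g)
  dge <- edgeR::estimateDisp(dge, design)
  ref <- edgeR::glmLRT(edgeR::glmFit(dge, design))
  expect_gt(cor(mine$p, ref$table$PValue, method = "spearman",
                use = "complete.obs"), 0.99)
  expect_gt(cor(mine$log2FC, ref$table$logFC), 0.999)
})
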