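test_that("intensity rescaling is exact division and composes", {
  img <- matrix(100, 8, 8)
  expect_identical(rescaleIntensity(img, 1), img)
  expect_true(all(rescaleIntensity(img, 4) == 25))
  rnd <- matrix(runif(64, 0, 1000), 8)
  expect_equal(rescaleIntensity(rescaleIntensity(rnd, 2.5), 4),
               rescaleIntensity(rnd, 10))
  expect_error(rescaleIntensity(img, 0), "positive")
})

test_that("Otsu separates bimodal images and matches the exhaustive oracle", {
  img <- matrix(c(rep(0, 50), rep(200, 50)), 10)
  thr <- otsuThreshold(img)
  expect_gt(thr, 0)
  expect_lt(thr, 200)
  expect_equal(sum(img > thr), 50)

  set.seed(42)
  for (i in 1:25) {
    nb <- sample(8:32, 1)
    counts <- rpois(nb, exp(runif(nb, 0, 5)))
    if (sum(counts > 0) < 2) next
    mids <- seq(0, 255, length.out = nb)
    h <- list(counts = counts, mids = mids)
    expect_identical(otsuThreshold(h), oracleOtsu(counts, mids))
  }

  # scaling all intensities scales the threshold (same binning rule)
  set.seed(7)
  v <- c(rnorm(300, 40, 8), rnorm(200, 160, 15))
  expect_equal(otsuThreshold(v * 3.5), 3.5 * otsuThreshold(v))
  expect_error(otsuThreshold(matrix(5, 4, 4)), "constant")
})

test_that("nuclear segmentation finds well-separated nuclei near truth", {
  blank <- matrix(100, 32, 32)
  expect_warning(m0 <- segmentNuclei(blank), "no nuclei")
  expect_equal(nObjects(m0), 0L)

  f <- generateField(fieldSpec(nCells = 10L, imageSize = c(384L, 384L),
                               noiseSd = 10), seed = 13)
  nuc <- segmentNuclei(nuclearChannel(f))
  expect_equal(nObjects(nuc), 10L)
  lab <- labels2d(nuc)
  tc <- truthCells(f)
  for (k in seq_len(10)) {
    px <- which(lab == k, arr.ind = TRUE)
    cen <- colMeans(px)
    d <- sqrt((tc$row - cen[1])^2 + (tc$col - cen[2])^2)
    expect_lt(min(d), 2)
  }
})

test_that("nuclei joined by a one-pixel bridge merge into one object", {
  img <- matrix(100, 80, 80)
  for (ctr in list(c(40, 25), c(40, 55)))
    img[oracleEllipsePixels(ctr[1], ctr[2], 6, 6, 0, c(80L, 80L))] <- 1000
  img[40, 25:55] <- 1000  # 1-px bridge
  nuc <- segmentNuclei(img, minArea = 20)
  expect_equal(nObjects(nuc), 1L)
})

test_that("propagation from seeds respects geometry and containment", {
  # one nucleus in a uniform disk: the cell is the foreground disk
  img <- matrix(0, 100, 100)
  disk <- oracleEllipsePixels(50, 50, 30, 30, 0, c(100L, 100L))
  img[disk] <- 500
  seed <- mkLabelMask(list(oracleEllipsePixels(50, 50, 6, 6, 0, c(100L, 100L))),
                      c(100L, 100L), "nuclei")
  cells <- segmentCells(img, seed)
  expect_equal(nObjects(cells), 1L)
  fg <- img > otsuThreshold(img)
  expect_gt(sum(labels2d(cells) == 1 & fg) / sum(fg), 0.98)

  # two equidistant nuclei in a uniform rectangle: boundary at the bisector
  rect <- matrix(0, 120, 90)
  rect[11:110, 11:80] <- 500
  seeds <- mkLabelMask(list(oracleEllipsePixels(60, 25, 5, 5, 0, c(120L, 90L)),
                            oracleEllipsePixels(60, 65, 5, 5, 0, c(120L, 90L))),
                       c(120L, 90L), "nuclei")
  cells2 <- segmentCells(rect, seeds)
  lab <- labels2d(cells2)
  bisector <- 45
  inRect <- which(rect > 0, arr.ind = TRUE)
  away <- inRect[abs(inRect[, 2] - bisector) > 2, ]
  got <- lab[away]
  want <- ifelse(away[, 2] < bisector, 1L, 2L)
  expect_gt(mean(got == want), 0.99)

  # every nucleus pixel inherits its own cell's label
  expect_true(all(lab[labels2d(seeds) == 1] == 1))
  expect_true(all(lab[labels2d(seeds) == 2] == 2))
  expect_error(segmentCells(matrix(0, 10, 10), seeds), "dimensions")
})

test_that("cells and nuclei are in bijection on synthetic fields", {
  f <- generateField(fieldSpec(nCells = 12L, imageSize = c(420L, 420L)),
                     seed = 31)
  nuc <- segmentNuclei(nuclearChannel(f))
  cells <- segmentCells(reporterChannel(f), nuc)
  expect_equal(nObjects(cells), nObjects(nuc))
  nl <- labels2d(nuc); cl <- labels2d(cells)
  for (k in seq_len(nObjects(nuc))) {
    under <- unique(cl[nl == k])
    expect_identical(under, k)
  }
})

test_that("top-hat focus detection is size selective", {
  flat <- matrix(500, 64, 64)
  expect_equal(nObjects(detectFoci(flat)), 0L)

  img <- matrix(500, 80, 80)
  disk <- oracleEllipsePixels(40, 40, 3, 3, 0, c(80L, 80L))
  img[disk] <- 1500
  det <- detectFoci(img, speckleRadius = 6)
  expect_equal(nObjects(det), 1L)
  expect_lt(abs(sum(labels2d(det) > 0) - nrow(disk)) / nrow(disk), 0.15)

  # structures wider than the element are suppressed
  big <- matrix(500, 80, 80)
  big[oracleEllipsePixels(40, 40, 12, 12, 0, c(80L, 80L))] <- 1500
  expect_equal(nObjects(detectFoci(big, speckleRadius = 6)), 0L)

  expect_error(detectFoci(img, thresholdMode = "manual"), "manualThreshold")
  # manual threshold path finds the same focus
  detM <- detectFoci(img, speckleRadius = 6, thresholdMode = "manual",
                     manualThreshold = 500)
  expect_equal(nObjects(detM), 1L)
})

test_that("eccentricity filter matches analytic ellipse values", {
  dim <- c(60L, 200L)
  shapes <- list(oracleEllipsePixels(30, 30, 15, 15, 0, dim),
                 oracleEllipsePixels(30, 95, 15, 9, 0.4, dim),
                 oracleEllipsePixels(30, 165, 15, 6, 1.2, dim))
  mask <- mkLabelMask(shapes, dim)
  img <- matrix(1, dim[1], dim[2])
  all3 <- filterFoci(mask, img, maxEccentricity = 1)
  expect_equal(nrow(all3), 3)
  expected <- c(0, sqrt(1 - 0.6^2), sqrt(1 - 0.4^2))
  expect_true(all(abs(all3$eccentricity - expected) < 0.03))
  kept <- filterFoci(mask, img, maxEccentricity = 0.875)
  expect_equal(nrow(kept), 2)
  # monotonicity: a looser filter never retains fewer foci
  nKept <- vapply(c(0.3, 0.6, 0.875, 0.95, 1), function(e)
    nrow(filterFoci(mask, img, maxEccentricity = e)), numeric(1))
  expect_true(all(diff(nKept) >= 0))
})

test_that("focus assignment handles empty, matched and background cases", {
  f <- generateField(fieldSpec(nCells = 10L, imageSize = c(384L, 384L)),
                     seed = 17)
  res <- quantifyField(nuclearChannel(f), reporterChannel(f))
  ml <- matchCells(f, res$cells)
  tc <- truthCells(f)
  expect_gte(mean(res$cellTable$foci_count[ml] == tc$foci_count), 0.9)

  emptyFoci <- filterFoci(mkLabelMask(list(), c(384L, 384L)),
                          reporterChannel(f))
  z <- assignAndSummarize(emptyFoci, res$cells, reporterChannel(f))
  expect_true(all(z$cellTable$foci_count == 0))
  expect_true(all(z$cellTable$total_foci_area == 0))
  expect_false(any(z$cellTable$has_foci))

  # focus centered on background goes to the unassigned tally
  bgFocus <- data.frame(focus_id = 1L, cell_id = 0L, area = 10,
                        eccentricity = 0, row = 2, col = 2,
                        mean_intensity = 1)
  u <- assignAndSummarize(bgFocus, res$cells, reporterChannel(f))
  expect_equal(u$nUnassigned, 1L)
  expect_true(all(u$cellTable$foci_count == 0))
})

test_that("condition summaries average replicate-level statistics", {
  mk <- function(cond, rep, n, nFoci) data.frame(
    condition = cond, replicate = rep,
    foci_count = c(rep(1L, nFoci), rep(0L, n - nFoci)),
    total_foci_area = c(rep(30, nFoci), rep(0, n - nFoci)))
  one <- summarizeCondition(mk("A", 1, 100, 40))
  expect_equal(one$pct_cells_with_foci, 40)
  expect_true(is.na(one$pct_sem))
  expect_true(one$flag_few_replicates)

  three <- summarizeCondition(rbind(mk("A", 1, 100, 40), mk("A", 2, 100, 50),
                                    mk("A", 3, 100, 60)))
  expect_equal(three$pct_cells_with_foci, 50)
  expect_equal(three$pct_sem, 10 / sqrt(3))
  expect_equal(three$n_replicates, 3)
  expect_false(three$flag_few_replicates)
  expect_false(three$flag_low_cells)
  low <- summarizeCondition(rbind(mk("A", 1, 50, 10), mk("A", 2, 120, 20),
                                  mk("A", 3, 120, 20)))
  expect_true(low$flag_low_cells)

  zero <- summarizeCondition(rbind(mk("A", 1, 100, 0), mk("A", 2, 100, 0),
                                   mk("A", 3, 100, 0)))
  expect_equal(zero$pct_cells_with_foci, 0)
})

test_that("rank-based condition comparison behaves at the null and extremes", {
  vals <- c(rnorm(100, 10), rnorm(100, 10))
  grp <- rep(c("ref", "same"), each = 100)
  vals[101:200] <- vals[1:100]  # identical populations
  same <- compareConditions(vals, grp, "ref")
  expect_gt(same$p, 0.99)
  expect_equal(same$tier, "ns")

  sep <- compareConditions(c(1:100, 201:300),
                           rep(c("ref", "hi"), each = 100), "ref")
  expect_lt(sep$p, 1e-30)
  expect_gt(sep$p, 0)
  expect_equal(sep$tier, "****")

  expect_equal(sgribo:::significanceTier(c(0.03, 0.007, 5e-4, 5e-5, 0.2)),
               c("*", "**", "***", "****", "ns"))
  expect_error(compareConditions(vals, grp, "missing"), "reference")
})

test_that("expression-deviation check flags beyond 25 percent strictly", {
  vals <- c(rep(100, 50), rep(130, 50), rep(125, 50), rep(100, 50))
  grp <- rep(c("WT", "thirty", "boundary", "same"), each = 50)
  d <- checkExpressionDeviation(vals, grp, "WT")
  expect_equal(d$deviation[d$condition == "same"], 0)
  expect_false(d$flagged[d$condition == "same"])
  expect_equal(d$deviation[d$condition == "thirty"], 0.30)
  expect_true(d$flagged[d$condition == "thirty"])
  expect_equal(d$deviation[d$condition == "boundary"], 0.25)
  expect_false(d$flagged[d$condition == "boundary"])
  expect_error(checkExpressionDeviation(c(0, 0, 1), c("a", "a", "b"), "a"),
               "zero")
})
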