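test_that("empty and zero-foci fields are rendered as degenerate cases", {
  spec0 <- fieldSpec(nCells = 0L, imageSize = c(64L, 64L), noiseSd = 0)
  f0 <- generateField(spec0, seed = 1)
  expect_equal(nrow(truthCells(f0)), 0)
  expect_equal(nrow(truthFoci(f0)), 0)
  expect_true(all(nuclearChannel(f0) == 100))
  expect_true(all(reporterChannel(f0) == 100))

  specNF <- fieldSpec(nCells = 10L, fociPerCell = 0,
                      imageSize = c(320L, 320L), cellRadius = c(24, 2))
  fNF <- generateField(specNF, seed = 2)
  expect_equal(nrow(truthFoci(fNF)), 0)
  expect_true(all(truthCells(fNF)$foci_count == 0))
})

test_that("truth foci areas equal independently counted rendered-disk pixels", {
  spec <- fieldSpec(nCells = 5L, fociPerCell = 4, fociExact = TRUE,
                    focusRadius = c(3, 0), focusAxisRatio = 1,
                    imageSize = c(300L, 300L), noiseSd = 0)
  f <- generateField(spec, seed = 3)
  tf <- truthFoci(f)
  expect_equal(nrow(tf), 20)
  oracleAreas <- vapply(seq_len(nrow(tf)), function(i)
    nrow(oracleEllipsePixels(tf$row[i], tf$col[i], 3, 3, 0, c(300L, 300L))),
    numeric(1))
  expect_equal(tf$area, oracleAreas)
  tc <- truthCells(f)
  for (id in tc$cell_id) {
    expect_equal(tc$foci_count[tc$cell_id == id], 4L)
    expect_equal(sum(tf$area[tf$cell_id == id]),
                 sum(oracleAreas[tf$cell_id == id]))
  }
})

test_that("rendered focus geometry matches the truth table", {
  # foci large enough that moment eccentricity is not quantization-limited
  f <- generateField(fieldSpec(nCells = 8L, imageSize = c(384L, 384L),
                               focusRadius = c(10, 0.8), fociPerCell = 2),
                     seed = 11)
  tf <- truthFoci(f)
  expect_gt(nrow(tf), 0)
  for (i in seq_len(nrow(tf))) {
    px <- oracleEllipsePixels(tf$row[i], tf$col[i], tf$a[i], tf$b[i],
                              tf$theta[i], c(384L, 384L))
    expect_lte(abs(nrow(px) - tf$area[i]), 1)
    mask <- matrix(0L, 384, 384)
    mask[px] <- 1L
    meas <- sgribo:::regionMoments(mask)
    expect_lt(abs(meas$eccentricity - tf$eccentricity[i]), 0.03)
  }
  expect_true(all(tf$eccentricity == sqrt(1 - (tf$b / tf$a)^2)))
  # foci lie inside their cell's disk
  tc <- truthCells(f)
  for (i in seq_len(nrow(tf))) {
    cell <- tc[tc$cell_id == tf$cell_id[i], ]
    d <- sqrt((tf$row[i] - cell$row)^2 + (tf$col[i] - cell$col)^2)
    expect_lte(d + tf$a[i], cell$radius)
  }
})

test_that("field generation is bit-reproducible and leaves the RNG alone", {
  spec <- fieldSpec(nCells = 6L, imageSize = c(200L, 200L),
                    cellRadius = c(25, 2))
  set.seed(99)
  before <- .Random.seed
  f1 <- generateField(spec, seed = 5)
  expect_identical(before, .Random.seed)
  f2 <- generateField(spec, seed = 5)
  expect_identical(nuclearChannel(f1), nuclearChannel(f2))
  expect_identical(reporterChannel(f1), reporterChannel(f2))
  expect_identical(truthFoci(f1), truthFoci(f2))
})

test_that("impossible placement fails with an informative error", {
  spec <- fieldSpec(nCells = 60L, imageSize = c(100L, 100L),
                    cellRadius = c(30, 1))
  expect_error(generateField(spec, seed = 1), "without overlap")
})

test_that("timecourse foci follow the condensation window with fixed cells", {
  spec <- fieldSpec(nCells = 6L, imageSize = c(256L, 256L),
                    timepoints = c(0, 180, 600),
                    condensationOnset = 120, condensationOffset = 240)
  tc <- generateTimecourse(spec, seed = 7)
  counts <- vapply(tc, function(f) nrow(truthFoci(f)), integer(1))
  expect_equal(counts[1], 0L)
  expect_gt(counts[2], 0L)
  expect_equal(counts[3], 0L)
  pos <- lapply(tc, function(f) truthCells(f)[, c("row", "col", "radius")])
  expect_identical(pos[[1]], pos[[2]])
  expect_identical(pos[[1]], pos[[3]])

  # a single pre-onset timepoint is identical to a zero-foci render
  spec1 <- fieldSpec(nCells = 6L, imageSize = c(256L, 256L),
                     timepoints = 0, condensationOnset = 120,
                     condensationOffset = 240)
  spec1z <- fieldSpec(nCells = 6L, imageSize = c(256L, 256L),
                      timepoints = 0, fociPerCell = 0,
                      condensationOnset = 120, condensationOffset = 240)
  a <- generateTimecourse(spec1, seed = 9)[[1]]
  b <- generateField(spec1z, seed = 9, timepoint = 0)
  expect_identical(reporterChannel(a), reporterChannel(b))
  expect_identical(nuclearChannel(a), nuclearChannel(b))

  tcBis <- generateTimecourse(spec, seed = 7)
  expect_identical(reporterChannel(tc[[2]]), reporterChannel(tcBis[[2]]))
})

test_that("count generator matches its design in mean and determinism", {
  des <- countDesign(nGenes = 2000L, classes = c(TE_UP = 0L),
                     sizeFactors = rep(1, 12), seed = 21L)
  se <- generateCounts(des)
  cnt <- SummarizedExperiment::assay(se, "counts")
  q <- SummarizedExperiment::rowData(se)$baseline_mean
  for (s in seq_len(ncol(cnt))) {
    seCol <- sd(cnt[, s]) / sqrt(nrow(cnt))
    expect_lt(abs(mean(cnt[, s]) - mean(q)), 3 * seCol)
  }
  expect_true(all(cnt == floor(cnt)) && all(cnt >= 0))
  se2 <- generateCounts(des)
  expect_identical(SummarizedExperiment::assay(se2, "counts"), cnt)
})

test_that("planted TE_UP genes shift only the stressed Ribo means", {
  des <- countDesign(nGenes = 20L, classes = c(TE_UP = 5L), effectLfc = 2,
                     baselineMean = 100, dispersion = 0.05,
                     sizeFactors = rep(1, 12), seed = 4L)
  se <- generateCounts(des)
  mu <- SummarizedExperiment::assay(se, "mu")
  cd <- SummarizedExperiment::colData(se)
  truth <- SummarizedExperiment::rowData(se)
  i <- which(truth$class == "TE_UP")[1]
  riboStress <- mu[i, cd$assay == "RIBO" & cd$condition == "stress"]
  riboCtrl <- mu[i, cd$assay == "RIBO" & cd$condition == "control"]
  rnaStress <- mu[i, cd$assay == "RNA" & cd$condition == "stress"]
  rnaCtrl <- mu[i, cd$assay == "RNA" & cd$condition == "control"]
  expect_equal(unname(riboStress / riboCtrl), rep(4, 3))
  expect_equal(unname(rnaStress), unname(rnaCtrl))
})

test_that("per-gene count means agree with the design over replicate draws", {
  des <- countDesign(nGenes = 40L, classes = c(TE_UP = 0L), baselineMean = 80,
                     dispersion = 0.1, nReplicates = 2L,
                     sizeFactors = rep(1, 8))
  mu <- SummarizedExperiment::assay(generateCounts(des), "mu")
  reps <- vapply(1:200, function(s) {
    rowMeans(SummarizedExperiment::assay(generateCounts(des, seed = 1000 + s),
                                         "counts"))
  }, numeric(40))
  grandMean <- rowMeans(reps)
  seMean <- apply(reps, 1, sd) / sqrt(200)
  expect_true(all(abs(grandMean - rowMeans(mu)) < 5 * pmax(seMean, 1e-8)))
})

test_that("count design validation rejects bad inputs", {
  expect_error(countDesign(nGenes = 10L, dispersion = -1), "positive")
  expect_error(countDesign(nGenes = 10L, sizeFactors = rep(0, 12)),
               "positive")
  expect_error(countDesign(nGenes = 10L, nReplicates = 1L), "replicates")
  expect_error(countDesign(nGenes = 10L, classes = c(BOGUS = 2L)), "unknown")
})

test_that("melt curves are logistic on the instrument grid", {
  mc <- generateMeltCurve(50, noiseSd = 0)
  expect_equal(nrow(mc), (95 - 25) / 0.2 + 1)
  expect_equal(mc$temperature[2] - mc$temperature[1], 0.2)
  d <- diff(mc$fluorescence)
  peakT <- mc$temperature[which.max(d)]
  expect_lte(abs(peakT - 50), 0.2 + 1e-9)
  # steeper transitions sharpen the derivative peak
  d2 <- diff(generateMeltCurve(50, steepness = 4, noiseSd = 0)$fluorescence)
  expect_gt(max(d2), max(d))
  expect_error(generateMeltCurve(20), "\\[25, 95\\]")
})
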