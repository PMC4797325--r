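test_that("intensity flooring raises only sub-threshold values", {
  expect_equal(floorIntensities(c(0.2, 1.0, 57.3)), c(1, 1, 57.3))
  batch <- makeOneArray(M = c(0, 0), A = c(-2, 8))  # first probe dim: cy < 1
  floored <- floorIntensities(batch)
  expect_true(all(cy3(floored) >= 1) && all(cy5(floored) >= 1))
  expect_equal(cy3(floored)[2, 1], cy3(batch)[2, 1])
  # flooring then log-ratio keeps entries finite even for zero intensities
  expect_true(all(is.finite(log2(cy3(floored) / cy5(floored)))))
})

test_that("a constant dye bias is fully absorbed by the Lowess trend", {
  set.seed(1)
  A <- runif(2000, 6, 12)
  batch <- makeOneArray(M = rep(1, 2000), A = A)  # cy3 = 2 * cy5 everywhere
  expect_equal(unname(cy3(batch)[, 1] / cy5(batch)[, 1]), rep(2, 2000))
  se <- lowessNormalize(batch)
  expect_lt(max(abs(SummarizedExperiment::assay(se, "M"))), 1e-6)
})

test_that("Lowess is near-identity on trend-free input and idempotent on null input", {
  set.seed(2)
  n <- 5000
  A <- runif(n, 6, 12)
  M <- rnorm(n, 0, 0.25)
  se <- lowessNormalize(makeOneArray(M = M, A = A))
  rmse <- sqrt(mean((SummarizedExperiment::assay(se, "M")[, 1] - M)^2))
  expect_lt(rmse, 0.02)
  # exact-null input: a second pass changes nothing measurable
  batch0 <- makeOneArray(M = rep(0.3, n), A = A)
  se1 <- lowessNormalize(batch0)
  M1 <- SummarizedExperiment::assay(se1, "M")[, 1]
  se2 <- lowessNormalize(makeOneArray(M = M1, A = A))
  expect_lt(max(abs(SummarizedExperiment::assay(se2, "M")[, 1] - M1)), 1e-6)
})

test_that("Lowess recovers planted signal under a sinusoidal dye bias at 40k probes", {
  set.seed(3)
  n <- 40000
  A <- runif(n, 6, 12)
  signal <- rnorm(n, 0, 0.25)
  observed <- signal + 0.5 * sin(A)
  se <- lowessNormalize(makeOneArray(M = observed, A = A))
  rmse <- sqrt(mean((SummarizedExperiment::assay(se, "M")[, 1] - signal)^2))
  expect_lt(rmse, 0.05)
})

test_that("Lowess refuses arrays with too few usable probes", {
  batch <- makeOneArray(M = rep(0, 5), A = 1:5)
  expect_error(lowessNormalize(batch), "fewer than 10")
})

test_that("the 75%-in-any-two-groups retention rule works probe by probe", {
  # rows: above-background array counts per group (WW, WD, DW, DD)
  pattern <- rbind(
    both_pure  = c(6, 0, 0, 6),  # two full groups -> retained
    one_group  = c(6, 0, 0, 0),  # a single group  -> removed
    two_at_5   = c(5, 5, 0, 0),  # ceil(0.75*6)=5  -> retained
    two_at_4   = c(4, 6, 0, 0),  # 4 < 5 in WW     -> removed
    everywhere = c(6, 6, 6, 6))
  batch <- makeFlagBatch(pattern)
  expect_equal(qcFilter(batch), c("p001", "p003", "p005"))
})

test_that("controls, saturated and outlier probes are removed globally", {
  pattern <- matrix(6, 4, 4)  # all probes above background everywhere
  sat <- out <- matrix(FALSE, 4, 24)
  sat[2, 13] <- TRUE   # saturated on a single array
  out[3, 2] <- TRUE    # population outlier on a single array
  batch <- makeFlagBatch(pattern, isControl = c(FALSE, FALSE, FALSE, TRUE),
                         saturated = sat, outlier = out)
  expect_equal(qcFilter(batch), "p001")
  expect_error(qcFilter(batch, fracThreshold = 0), "\\(0, 1\\]")
  expect_error(qcFilter(batch, fracThreshold = 1.2), "\\(0, 1\\]")
})

test_that("qc filter is monotone in the threshold and invariant to column order", {
  set.seed(4)
  nP <- 200
  above <- matrix(runif(nP * 24) < 0.7, nP, 24)
  batch <- makeFlagBatch(matrix(0, nP, 4))
  batch@aboveBackground <- above
  kept <- lapply(c(0.25, 0.5, 0.75, 1), function(f) qcFilter(batch, f))
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
  perm <- sample(24)
  expect_equal(qcFilter(batch[, perm]), qcFilter(batch))
})

test_that("feature tables round-trip through the writer and reader", {
  dir <- withr::local_tempdir()
  sim <- simulateExperiment(
    simConfig(nGenes = 120, nDEGenes = 30, nControls = 10, nGeneSets = 4,
              plantedSetSpec = list(list(direction = "up", shift = 1,
                                         size = 15)),
              seed = 1),
    dir = dir)
  batch <- readFeatureTables(sim$paths$sampleSheet)
  expect_equal(probeData(batch)$probe_id, probeData(sim$batch)$probe_id)
  expect_equal(cy3(batch), cy3(sim$batch), tolerance = 1e-6)
  expect_equal(cy5(batch), cy5(sim$batch), tolerance = 1e-6)
  expect_identical(batch@aboveBackground, sim$batch@aboveBackground)
  expect_identical(batch@saturated, sim$batch@saturated)
  keep <- c("array_id", "cross_type", "replicate", "slide_id")
  expect_equal(as.data.frame(sampleData(batch))[keep],
               as.data.frame(sampleData(sim$batch))[keep])
})

test_that("mismatched probe universes and bad labels are hard errors", {
  dir <- withr::local_tempdir()
  for (arr in c("a1", "a2")) {
    probes <- if (arr == "a1") c("A", "B", "C") else c("A", "B", "D")
    write.table(
      data.frame(probe_id = probes, cy3 = 10, cy5 = 10, is_control = FALSE,
                 flag_saturated = FALSE, flag_outlier = FALSE,
                 flag_above_background = TRUE),
      file.path(dir, paste0(arr, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sheet <- data.frame(array_id = c("a1", "a2"),
                      file = c("a1.tsv", "a2.tsv"),
                      cross_type = c("WW", "DD"), replicate = c(1, 1),
                      slide_id = c("s1", "s2"))
  path <- file.path(dir, "sheet.tsv")
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readFeatureTables(path), "a2.*C|C.*a2")
  sheet$file <- "a1.tsv"
  sheet$cross_type <- c("WW", "XX")
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readFeatureTables(path), "XX")
})

test_that("missing flag columns default to passing with a warning", {
  dir <- withr::local_tempdir()
  write.table(
    data.frame(probe_id = sprintf("p%02d", 1:12), cy3 = 10, cy5 = 20,
               is_control = FALSE),
    file.path(dir, "a1.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(array_id = "a1", file = "a1.tsv", cross_type = "WW",
                      replicate = 1, slide_id = "s1")
  path <- file.path(dir, "sheet.tsv")
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(batch <- readFeatureTables(path), "defaulting")
  expect_true(all(batch@aboveBackground))
  expect_false(any(batch@saturated))
})
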