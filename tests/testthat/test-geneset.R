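test_that("GMT files round-trip with their functional groups", {
  dir <- withr::local_tempdir()
  sets <- list(pathA = c("g1", "g2", "g3"), pathB = c("g2", "g9"))
  groups <- c(pathA = "Metabolism", pathB = "Human Diseases")
  path <- file.path(dir, "sets.gmt")
  writeGMT(sets, groups, path)
  got <- readGMT(path)
  expect_equal(got$sets, sets)
  expect_equal(got$groups, groups)
})

test_that("one-on-group fold changes subtract the control-group mean", {
  set.seed(50)
  M <- matrix(rnorm(100 * 12), 100, 12)
  se <- makeCE2(M, nRep = 6)  # 1:6 WW (control), 7:12 DD (test)
  fc <- oneOnGroupFoldChanges(se)
  expect_equal(dim(fc), c(100, 6))
  # independent oracle: per-gene loop
  for (j in 1:6) {
    want <- sapply(1:100, function(g) M[g, 6 + j] - mean(M[g, 1:6]))
    expect_equal(unname(fc[, j]), want)
  }
  # a test replicate equal to the control mean gives an all-zero column
  M2 <- M
  M2[, 7] <- rowMeans(M2[, 1:6])
  fc2 <- oneOnGroupFoldChanges(makeCE2(M2, nRep = 6))
  expect_equal(unname(fc2[, 1]), rep(0, 100))
})

test_that("the set-vs-all t-test detects shifts in the planted direction only", {
  set.seed(51)
  fc <- rnorm(5000, 0, 0.3)
  names(fc) <- sprintf("g%04d", 1:5000)
  members <- names(fc)[1:50]
  fc[members] <- fc[members] + 1
  expect_lt(gageSetTest(fc, members, "up"), 1e-10)
  expect_gt(gageSetTest(fc, members, "down"), 0.5)
  # null set: one-sided p is near 1/2
  nullMembers <- names(fc)[101:400]
  expect_gt(gageSetTest(fc, nullMembers, "up"), 0.2)
  expect_lt(gageSetTest(fc, nullMembers, "up"), 0.8)
  # degenerate variance convention
  expect_equal(gageSetTest(rep(0, 100) + setNames(numeric(100),
                                                  sprintf("g%d", 1:100)),
                           sprintf("g%d", 1:20), "up"), 1)
})

test_that("bidirectional perturbation is caught by the two-way test only", {
  set.seed(52)
  fc <- rnorm(5000, 0, 0.3)
  names(fc) <- sprintf("g%04d", 1:5000)
  members <- names(fc)[1:50]
  fc[members[1:25]] <- fc[members[1:25]] + 1
  fc[members[26:50]] <- fc[members[26:50]] - 1
  expect_gt(gageSetTest(fc, members, "up"), 0.01)
  expect_gt(gageSetTest(fc, members, "down"), 0.01)
  expect_lt(gageSetTest(fc, members, "two_way"), 1e-6)
  # two-way p is invariant to flipping signs of arbitrary genes
  flip <- sample(c(-1, 1), 5000, replace = TRUE)
  expect_equal(gageSetTest(fc * flip, members, "two_way"),
               gageSetTest(fc, members, "two_way"))
  # sign antisymmetry between up on X and down on -X
  expect_equal(gageSetTest(-fc, members, "down"),
               gageSetTest(fc, members, "up"))
})

test_that("Stouffer combination matches the probit formula", {
  expect_equal(combineComparisons(c(0.5, 0.5, 0.5)), 0.5)
  expect_lt(combineComparisons(rep(0.01, 6)), 0.01)
  expect_equal(combineComparisons(c(0.2, 0.04, 0.6)),
               oracleStouffer(c(0.2, 0.04, 0.6)), tolerance = 1e-10)
  expect_error(combineComparisons(numeric(0)), "empty")
  # the correlation correction widens the combined p toward the null
  expect_gt(combineComparisons(rep(0.01, 6), rho = 1 / 7),
            combineComparisons(rep(0.01, 6)))
})

test_that("combined null p-values are uniform once the shared control mean is accounted for", {
  set.seed(53)
  M <- matrix(rnorm(4000 * 12, sd = 0.3), 4000, 12)
  rownames(M) <- sprintf("g%04d", 1:4000)
  se <- makeCE2(M, nRep = 6)
  fc <- oneOnGroupFoldChanges(se)
  rho <- 1 / 7
  pc <- replicate(500, {
    members <- sample(rownames(M), 50)
    pj <- apply(fc, 2, gageSetTest, members = members, direction = "up")
    combineComparisons(pj, rho = rho)
  })
  expect_gt(suppressWarnings(ks.test(pc, "punif"))$p.value, 0.01)
  # the combined z-scores are near-standard with the correction and
  # overdispersed without it (shared control mean, rho = 1/7 -> var 12/7)
  expect_lt(abs(var(qnorm(1 - pc)) - 1), 0.25)
  pu <- replicate(300, {
    members <- sample(rownames(M), 50)
    pj <- apply(fc, 2, gageSetTest, members = members, direction = "up")
    combineComparisons(pj)
  })
  expect_gt(var(qnorm(1 - pu)), 1.3)
})

test_that("essential genes need both a 1-SD deviation and a per-gene test", {
  set.seed(54)
  M <- matrix(rnorm(500 * 12, sd = 0.25), 500, 12)
  M[1, 7:12] <- M[1, 7:12] + 2      # big shift, consistent -> both criteria
  M[2, 7:12] <- M[2, 7:12] + c(4, -1, 4, -2, 4, -1)  # big mean, noisy t
  se <- makeCE2(M, nRep = 6)
  ess <- essentialGenes(se, c("g0001", "g0002", "g0003"))
  expect_true("g0001" %in% ess)
  expect_false("g0002" %in% ess)
  expect_false("g0003" %in% ess)
  # null members qualify rarely (joint 1-SD and t-test criterion)
  rate <- length(essentialGenes(se, rownames(M)[-1])) / 499
  expect_lte(rate, 0.05)
})

test_that("primary function assignment picks the largest represented set", {
  sets <- list(big = sprintf("g%d", 1:40), small = c("g1", "g50"),
               absent = c("g1", "x1", "x2"))
  universe <- sprintf("g%d", 1:100)
  expect_equal(assignPrimaryFunction("g1", sets, universe), "big")
  expect_equal(assignPrimaryFunction("g50", sets["small"], universe),
               "small")
  tied <- list(b = c("g1", "g2"), a = c("g1", "g3"))
  expect_equal(assignPrimaryFunction("g1", tied, universe), "a")
  expect_error(assignPrimaryFunction("zz", sets, universe), "no candidate")
})

test_that("enrichment finds planted sets, honours exclusions and orderings", {
  sim <- simulateExperiment(
    simConfig(nGenes = 4000, nDEGenes = 200, annotatedFraction = 0.9,
              nGeneSets = 30, seed = 55))
  se <- lowessNormalize(sim$batch)
  se <- se[rownames(se) %in% qcFilter(sim$batch), ]
  se <- dropUnannotated(se, sim$annotation)
  p <- crossherit:::rowWelchT(SummarizedExperiment::assay(se, "M"),
                              crossColumns(se, "DD"),
                              crossColumns(se, "WW"))$p
  names(p) <- rownames(se)
  gse <- collapseToGenes(se, sim$annotation, p)
  enr <- runEnrichment(gse, sim$geneSets)
  up <- enr[enr$set_id == "path_planted_up_1", ]
  expect_true(up$significant[up$direction == "up"])
  expect_false(up$significant[up$direction == "down"])
  tw <- enr[enr$set_id == "path_planted_two_way_2", ]
  expect_true(tw$significant[tw$direction == "two_way"])
  expect_false(any(tw$significant[tw$direction != "two_way"]))
  expect_true(all(nzchar(
    enr$essential_genes[enr$significant & enr$set_id ==
                          "path_planted_up_1" & enr$direction == "up"])))
  # Human Diseases sets are excluded wholesale
  expect_false(any(enr$functional_group == "Human Diseases"))
  # excluding the planted set's group removes it from the results
  enr2 <- runEnrichment(gse, sim$geneSets,
                        excludeGroups = "Organismal Systems")
  expect_false("path_planted_up_1" %in% enr2$set_id)
  # qThreshold = 0 silences everything
  enr3 <- runEnrichment(gse, sim$geneSets, qThreshold = 0)
  expect_false(any(enr3$significant))
  # invariance to gene and set order
  perm <- sample(nrow(gse))
  sets2 <- sim$geneSets
  ord <- rev(seq_along(sets2$sets))
  sets2$sets <- sets2$sets[ord]; sets2$groups <- sets2$groups[ord]
  enr4 <- runEnrichment(gse[perm, ], sets2)
  enr4 <- enr4[match(paste(enr$set_id, enr$direction),
                     paste(enr4$set_id, enr4$direction)), ]
  expect_equal(enr4$p_raw, enr$p_raw, tolerance = 1e-12)
})
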