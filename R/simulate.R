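#' Configuration for a synthetic reciprocal-cross experiment
#'
#' Defaults emulate the study design this package targets: four cross types
#' (WW, WD, DW, DD) x six replicate common-reference two-colour arrays,
#' multiple probes per gene, technical controls, saturated and low-signal
#' probes, ~62 % annotated genes, 500 genes planted with differential
#' expression of 1.0 log2 units between the stocks and known inheritance
#' modes, plus planted perturbed gene sets among null sets.
#'
#' @param nGenes total genes on the array.
#' @param nDEGenes genes planted as differentially expressed between the
#'   stocks, carrying an inheritance mode.
#' @param probesPerGene vector of possible probe counts per gene, sampled
#'   uniformly.
#' @param nControls technical control probes.
#' @param annotatedFraction fraction of genes with gene/KO annotation.
#' @param replicatesPerCross arrays per cross type.
#' @param noiseSd replicate noise SD on the log2 scale.
#' @param modeProportions named 5-vector of planted inheritance-class
#'   proportions (wild over-dominant, wild dominant, additive, domesticated
#'   dominant, domesticated over-dominant), summing to 1, applied to the
#'   non-maternal DE genes.
#' @param effectSize |log2| expression difference between the pure stocks
#'   for planted genes.
#' @param maternalGeneFraction fraction of DE genes that are maternally
#'   determined (each hybrid matches its dam's line).
#' @param nGeneSets null gene sets.
#' @param plantedSetSpec list of planted perturbed sets, each a list with
#'   \code{direction} (up/down/two_way), \code{shift} (|log2| member shift)
#'   and \code{size}.
#' @param dyeBiasAmplitude amplitude of the intensity-dependent dye bias
#'   (injected as amplitude * sin(A) on the M scale).
#' @param saturatedFraction,outlierFraction,lowSignalFraction fractions of
#'   gene probes planted as saturated on one array, flagged as population
#'   outliers, or never above background.
#' @param swapLines exchange the wild and domesticated parental means while
#'   keeping the same random draws; planted wild/domesticated classes flip
#'   accordingly in the truth record.
#' @param seed RNG seed; everything the generator emits is deterministic
#'   given the config.
#' @return A validated \code{SimConfig} list.
#' @export
simConfig <- function(nGenes = 2000, nDEGenes = 500, probesPerGene = 1:3,
                      nControls = 100, annotatedFraction = 0.62,
                      replicatesPerCross = 6, noiseSd = 0.25,
                      modeProportions = c(wild_overdominant = 0.1,
                                          wild_dominant = 0.2,
                                          additive = 0.4,
                                          domesticated_dominant = 0.2,
                                          domesticated_overdominant = 0.1),
                      effectSize = 1.0, maternalGeneFraction = 0.2,
                      nGeneSets = 50,
                      plantedSetSpec = list(
                        list(direction = "up", shift = 1, size = 50),
                        list(direction = "two_way", shift = 1, size = 50)),
                      dyeBiasAmplitude = 0.3,
                      saturatedFraction = 0.01, outlierFraction = 0.005,
                      lowSignalFraction = 0.05, swapLines = FALSE,
                      seed = 11) {
  cfg <- list(nGenes = nGenes, nDEGenes = nDEGenes,
              probesPerGene = probesPerGene, nControls = nControls,
              annotatedFraction = annotatedFraction,
              replicatesPerCross = replicatesPerCross, noiseSd = noiseSd,
              modeProportions = modeProportions, effectSize = effectSize,
              maternalGeneFraction = maternalGeneFraction,
              nGeneSets = nGeneSets, plantedSetSpec = plantedSetSpec,
              dyeBiasAmplitude = dyeBiasAmplitude,
              saturatedFraction = saturatedFraction,
              outlierFraction = outlierFraction,
              lowSignalFraction = lowSignalFraction,
              swapLines = swapLines, seed = seed)
  if (any(modeProportions < 0) ||
      abs(sum(modeProportions) - 1) > 1e-8) {
    stop("modeProportions must be non-negative and sum to 1")
  }
  if (length(modeProportions) != 5L) {
    stop("modeProportions must have 5 entries")
  }
  fr <- c(annotatedFraction, maternalGeneFraction, saturatedFraction,
          outlierFraction, lowSignalFraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (nDEGenes > nGenes) stop("nDEGenes cannot exceed nGenes")
  if (noiseSd < 0 || effectSize < 0) stop("noiseSd/effectSize must be >= 0")
  structure(cfg, class = "SimConfig")
}

# deterministic largest-remainder allocation of n items to proportions
allocateCounts <- function(n, prop) {
  raw <- n * prop / sum(prop)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a complete synthetic reciprocal-cross experiment
#'
#' Draws per-gene baselines, plants stock differences and hybrid means
#' according to each gene's inheritance mode (additive = mid-parent;
#' dominant = one parent; over-dominant = outside the parental interval at
#' delta/alpha = +/-2; maternal = each hybrid at its dam's line mean),
#' converts log2 expression to Cy3/Cy5 channel intensities against a
#' common reference channel, injects an intensity-dependent dye bias, and
#' marks planted fractions of probes as controls, saturated, outliers or
#' never above background. A machine-readable truth record accompanies the
#' data. With \code{dir} given, the exact file dialects consumed by
#' \code{\link{readFeatureTables}}, \code{\link{readAnnotation}} and
#' \code{\link{readGMT}} are also written; regenerating with the same
#' config yields byte-identical files.
#'
#' @param config a \code{\link{simConfig}} object.
#' @param dir optional output directory (created if needed).
#' @return list with \code{batch} (\linkS4class{TwoColourArraySet}),
#'   \code{annotation}, \code{geneSets}, \code{truth} (lists
#'   \code{genes}, \code{sets}, \code{probes}), \code{config}, and
#'   \code{paths} when files were written.
#' @export
simulateExperiment <- function(config = simConfig(), dir = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  nG <- config$nGenes
  e <- config$effectSize
  geneIds <- sprintf("gene%05d", seq_len(nG))
  baseline <- stats::runif(nG, 6, 12)

  ## --- plant stock differences and hybrid means (log2 deviations) ---
  dev <- matrix(0, nG, 4, dimnames = list(geneIds, CROSS_TYPES))
  trueMode <- rep("null", nG)
  trueClassWD <- trueClassDW <- rep(NA_character_, nG)
  deIdx <- sample.int(nG, config$nDEGenes)
  nMat <- round(config$maternalGeneFraction * config$nDEGenes)
  matIdx <- deIdx[seq_len(nMat)]
  modeIdx <- setdiff(deIdx, matIdx)
  counts <- allocateCounts(length(modeIdx), config$modeProportions)
  modes <- sample(rep(CLASS_LEVELS, counts))
  s <- sample(c(-1, 1), nG, replace = TRUE)  # sign of D - W
  devW <- -s * e / 2
  devD <- s * e / 2
  dev[deIdx, "WW"] <- devW[deIdx]
  dev[deIdx, "DD"] <- devD[deIdx]
  hyb <- numeric(nG)  # common hybrid deviation for mode genes
  hyb[modeIdx] <- ifelse(modes == "additive", 0,
                  ifelse(modes == "wild_dominant", devW[modeIdx],
                  ifelse(modes == "domesticated_dominant", devD[modeIdx],
                  ifelse(modes == "wild_overdominant", -s[modeIdx] * e,
                         s[modeIdx] * e))))
  dev[modeIdx, "WD"] <- dev[modeIdx, "DW"] <- hyb[modeIdx]
  trueMode[modeIdx] <- modes
  trueClassWD[modeIdx] <- trueClassDW[modeIdx] <- modes
  dev[matIdx, "WD"] <- devW[matIdx]   # dam is wild
  dev[matIdx, "DW"] <- devD[matIdx]   # dam is domesticated
  trueMode[matIdx] <- "maternal"
  trueClassWD[matIdx] <- "wild_dominant"
  trueClassDW[matIdx] <- "domesticated_dominant"

  ## --- planted gene sets on extra stock-shifted genes (mid-parent hybrids) ---
  nullPool <- setdiff(seq_len(nG), deIdx)
  setTruth <- data.frame(set_id = character(), type = character(),
                         shift = numeric(), size = integer(),
                         functional_group = character(),
                         stringsAsFactors = FALSE)
  sets <- list(); setGroups <- character()
  geneSet <- rep("", nG)
  plantedIdx <- integer()
  for (k in seq_along(config$plantedSetSpec)) {
    spec <- config$plantedSetSpec[[k]]
    mem <- sample(setdiff(nullPool, plantedIdx), spec$size)
    plantedIdx <- c(plantedIdx, mem)
    sgn <- switch(spec$direction,
                  up = rep(1, spec$size),
                  down = rep(-1, spec$size),
                  two_way = rep(c(1, -1), length.out = spec$size),
                  stop("unknown planted set direction: ", spec$direction))
    dev[mem, "DD"] <- sgn * spec$shift / 2
    dev[mem, "WW"] <- -sgn * spec$shift / 2
    # hybrids stay at mid-parent (0): additive inheritance
    trueMode[mem] <- "set"
    trueClassWD[mem] <- trueClassDW[mem] <- "additive"
    id <- sprintf("path_planted_%s_%d", spec$direction, k)
    sets[[id]] <- geneIds[mem]
    setGroups[id] <- "Organismal Systems"
    geneSet[mem] <- id
    setTruth <- rbind(setTruth, data.frame(
      set_id = id, type = spec$direction, shift = spec$shift,
      size = spec$size, functional_group = "Organismal Systems",
      stringsAsFactors = FALSE))
  }
  groupCycle <- c("Cellular Processes", "Metabolism",
                  "Genetic Information Processing",
                  "Environmental Information Processing",
                  "Human Diseases")
  nullPool2 <- setdiff(nullPool, plantedIdx)
  szMax <- max(2L, min(80L, length(nullPool2)))
  szMin <- min(20L, szMax)
  for (k in seq_len(config$nGeneSets)) {
    sz <- sample(szMin:szMax, 1L)
    mem <- sample(nullPool2, sz)
    id <- sprintf("path_null_%03d", k)
    grp <- groupCycle[(k - 1L) %% length(groupCycle) + 1L]
    sets[[id]] <- geneIds[mem]
    setGroups[id] <- grp
    setTruth <- rbind(setTruth, data.frame(
      set_id = id, type = "null", shift = 0, size = sz,
      functional_group = grp, stringsAsFactors = FALSE))
  }

  if (isTRUE(config$swapLines)) {
    # exchange the parental lines: the new WW cross is the old DD cross,
    # the new WD hybrid the old DW hybrid; planted classes mirror
    dev <- dev[, c("DD", "DW", "WD", "WW")]
    colnames(dev) <- CROSS_TYPES
    mirror <- c(wild_overdominant = "domesticated_overdominant",
                wild_dominant = "domesticated_dominant",
                additive = "additive",
                domesticated_dominant = "wild_dominant",
                domesticated_overdominant = "wild_overdominant")
    swapCls <- function(x) ifelse(is.na(x), x, unname(mirror[x]))
    tmp <- trueClassWD
    trueClassWD <- swapCls(trueClassDW)
    trueClassDW <- swapCls(tmp)
    m5 <- trueMode %in% names(mirror)
    trueMode[m5] <- unname(mirror[trueMode[m5]])
    if (nrow(setTruth)) {
      setTruth$type <- unname(c(up = "down", down = "up",
                                two_way = "two_way",
                                null = "null")[setTruth$type])
    }
  }

  ## --- annotation (planted genes always annotated) ---
  forced <- sort(unique(c(deIdx, plantedIdx)))
  nAnn <- max(round(config$annotatedFraction * nG), length(forced))
  annIdx <- sort(c(forced,
                   sample(setdiff(seq_len(nG), forced),
                          nAnn - length(forced))))
  annotated <- seq_len(nG) %in% annIdx
  hasKo <- annotated & stats::runif(nG) < 0.7
  koId <- ifelse(hasKo, sprintf("K%05d", seq_len(nG)), "")

  ## --- probes ---
  k <- sample(config$probesPerGene, nG, replace = TRUE)
  geneOf <- rep.int(seq_len(nG), k)
  nP <- length(geneOf)
  probeIds <- sprintf("P%06d", seq_len(nP))
  affinity <- stats::rnorm(nP, 0, 0.5)
  fate <- sample(c("saturated", "outlier", "low_signal", "kept"), nP,
                 replace = TRUE,
                 prob = c(config$saturatedFraction, config$outlierFraction,
                          config$lowSignalFraction,
                          1 - config$saturatedFraction -
                            config$outlierFraction -
                            config$lowSignalFraction))

  ## --- arrays ---
  R <- config$replicatesPerCross
  cross <- rep(CROSS_TYPES, each = R)
  arrayIds <- sprintf("%s_r%02d", cross, rep(seq_len(R), times = 4))
  nA <- length(arrayIds)
  sheet <- data.frame(array_id = arrayIds, cross_type = cross,
                      replicate = rep(seq_len(R), times = 4),
                      slide_id = sprintf("slide%02d", seq_len(nA)),
                      stringsAsFactors = FALSE)

  ## --- channel intensities ---
  mTrue <- dev[geneOf, cross, drop = FALSE] +
    matrix(stats::rnorm(nP * nA, 0, config$noiseSd), nP, nA)
  A <- baseline[geneOf] + affinity +
    matrix(stats::rnorm(nP * nA, 0, 0.1), nP, nA)
  mObs <- mTrue + config$dyeBiasAmplitude * sin(A)
  cy3 <- 2^(A + mObs / 2)
  cy5 <- 2^(A - mObs / 2)
  satFlag <- outFlag <- matrix(FALSE, nP, nA)
  aboveFlag <- matrix(TRUE, nP, nA)
  iSat <- which(fate == "saturated")
  satFlag[cbind(iSat, sample.int(nA, length(iSat), replace = TRUE))] <- TRUE
  cy3[satFlag] <- cy5[satFlag] <- 65535
  iOut <- which(fate == "outlier")
  outFlag[cbind(iOut, sample.int(nA, length(iOut), replace = TRUE))] <- TRUE
  aboveFlag[fate == "low_signal", ] <- FALSE

  ## --- controls ---
  nC <- config$nControls
  if (nC > 0L) {
    cA <- stats::runif(nC, 6, 12) +
      matrix(stats::rnorm(nC * nA, 0, 0.1), nC, nA)
    cM <- matrix(stats::rnorm(nC * nA, 0, 0.5), nC, nA)
    cy3 <- rbind(cy3, 2^(cA + cM / 2))
    cy5 <- rbind(cy5, 2^(cA - cM / 2))
    satFlag <- rbind(satFlag, matrix(FALSE, nC, nA))
    outFlag <- rbind(outFlag, matrix(FALSE, nC, nA))
    aboveFlag <- rbind(aboveFlag, matrix(TRUE, nC, nA))
  }
  allIds <- c(probeIds, if (nC > 0L) sprintf("CTRL%04d", seq_len(nC)))
  isControl <- c(rep(FALSE, nP), rep(TRUE, nC))
  ord <- sample.int(length(allIds))  # shuffle probe order on the slide

  batch <- TwoColourArraySet(
    cy3 = cy3[ord, , drop = FALSE], cy5 = cy5[ord, , drop = FALSE],
    saturated = satFlag[ord, , drop = FALSE],
    outlier = outFlag[ord, , drop = FALSE],
    aboveBackground = aboveFlag[ord, , drop = FALSE],
    probeData = data.frame(probe_id = allIds[ord],
                           is_control = isControl[ord],
                           stringsAsFactors = FALSE),
    sampleData = sheet)

  annotation <- data.frame(
    probe_id = probeIds,
    gene_id = ifelse(annotated[geneOf], geneIds[geneOf], ""),
    ko_id = ifelse(annotated[geneOf], koId[geneOf], ""),
    stringsAsFactors = FALSE)

  truth <- list(
    genes = data.frame(
      gene_id = geneIds, baseline = baseline,
      is_de = seq_len(nG) %in% c(deIdx, plantedIdx),
      true_mode = trueMode,
      true_class_WD = trueClassWD, true_class_DW = trueClassDW,
      true_W = dev[, "WW"], true_D = dev[, "DD"],
      true_H_WD = dev[, "WD"], true_H_DW = dev[, "DW"],
      annotated = annotated, set_id = geneSet,
      stringsAsFactors = FALSE),
    sets = setTruth,
    probes = data.frame(
      probe_id = allIds,
      gene_id = c(geneIds[geneOf], rep("", nC)),
      qc_fate = c(fate, rep("control", nC)),
      stringsAsFactors = FALSE))

  out <- list(batch = batch, annotation = annotation,
              geneSets = list(sets = sets, groups = setGroups),
              truth = truth, config = config)
  if (!is.null(dir)) {
    out$paths <- writeSimulatedExperiment(out, dir)
  }
  out
}

# write the file dialects consumed by the readers
writeSimulatedExperiment <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  batch <- sim$batch
  sheet <- as.data.frame(sampleData(batch))
  files <- sprintf("array_%s.tsv", sheet$array_id)
  for (j in seq_len(nrow(sheet))) {
    tab <- data.frame(
      probe_id = probeData(batch)$probe_id,
      cy3 = cy3(batch)[, j],
      cy5 = cy5(batch)[, j],
      is_control = probeData(batch)$is_control,
      flag_saturated = batch@saturated[, j],
      flag_outlier = batch@outlier[, j],
      flag_above_background = batch@aboveBackground[, j],
      stringsAsFactors = FALSE)
    utils::write.table(tab, file.path(dir, files[j]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  sheetOut <- data.frame(array_id = sheet$array_id, file = files,
                         cross_type = sheet$cross_type,
                         replicate = sheet$replicate,
                         slide_id = sheet$slide_id,
                         stringsAsFactors = FALSE)
  paths <- list(
    sampleSheet = file.path(dir, "sample_sheet.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    truthGenes = file.path(dir, "truth_genes.tsv"),
    truthSets = file.path(dir, "truth_sets.tsv"),
    truthProbes = file.path(dir, "truth_probes.tsv"),
    featureTables = file.path(dir, files))
  utils::write.table(sheetOut, paths$sampleSheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$annotation, paths$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeGMT(sim$geneSets$sets, sim$geneSets$groups, paths$gmt)
  utils::write.table(sim$truth$genes, paths$truthGenes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$sets, paths$truthSets, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$probes, paths$truthProbes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Compare pipeline calls with the planted truth
#'
#' Joins heritability calls to the generator's per-gene, per-hybrid planted
#' classes and tabulates a confusion matrix (called over-dominance is split
#' into the wild/domesticated side by the sign of delta/alpha). Optionally
#' scores gene-set detection against the planted set truth.
#'
#' @param truth the \code{truth} element of a
#'   \code{\link{simulateExperiment}} result.
#' @param calls data.frame from \code{\link{heritabilityCalls}}.
#' @param enrichment optional data.frame from \code{\link{runEnrichment}}.
#' @return list with \code{confusion} (true x called table over genes with
#'   a planted class), \code{accuracy}, \code{perClass}
#'   (precision/recall), \code{n} and, when enrichment is given,
#'   \code{setDetection}.
#' @export
truthVsCalls <- function(truth, calls, enrichment = NULL) {
  if (!all(calls$gene_id %in% truth$genes$gene_id)) {
    stop("calls contain gene ids absent from the truth record")
  }
  tg <- truth$genes
  trueClass <- ifelse(calls$hybrid == "WD",
                      tg$true_class_WD[match(calls$gene_id, tg$gene_id)],
                      tg$true_class_DW[match(calls$gene_id, tg$gene_id)])
  called <- calls$mode
  called[called == "over_dominant" & calls$ratio < 0] <- "wild_overdominant"
  called[called == "over_dominant"] <- "domesticated_overdominant"
  use <- !is.na(trueClass) & called != "undefined"
  conf <- table(true = factor(trueClass[use], levels = CLASS_LEVELS),
                called = factor(called[use], levels = CLASS_LEVELS))
  acc <- if (any(use)) sum(diag(conf)) / sum(conf) else NA_real_
  perClass <- data.frame(
    class = CLASS_LEVELS,
    recall = diag(conf) / pmax(rowSums(conf), 1L),
    precision = diag(conf) / pmax(colSums(conf), 1L),
    row.names = NULL)
  out <- list(confusion = conf, accuracy = acc, perClass = perClass,
              n = sum(use))
  if (!is.null(enrichment)) {
    st <- truth$sets
    planted <- st[st$type != "null", , drop = FALSE]
    detected <- vapply(seq_len(nrow(planted)), function(i) {
      dir <- if (planted$type[i] == "two_way") "two_way" else planted$type[i]
      any(enrichment$set_id == planted$set_id[i] &
            enrichment$direction == dir & enrichment$significant)
    }, TRUE)
    nullSig <- sum(enrichment$significant &
                     enrichment$set_id %in% st$set_id[st$type == "null"])
    out$setDetection <- data.frame(planted,
                                   detected = detected,
                                   stringsAsFactors = FALSE)
    out$nullSetsSignificant <- nullSig
  }
  out
}
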