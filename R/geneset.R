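#' Read gene sets in GMT format
#'
#' One set per line: set id, description, then member genes, tab-separated.
#' The description field is kept as the set's functional group (e.g. the
#' KEGG top-level group), which drives group-based exclusions downstream.
#'
#' @param path GMT file.
#' @return list with \code{sets} (named list of character vectors) and
#'   \code{groups} (named character vector of functional groups).
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate set ids in GMT file")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- ids
  groups <- vapply(parts, `[`, "", 2L)
  names(groups) <- ids
  list(sets = sets, groups = groups)
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors of member genes.
#' @param groups named character vector of functional groups (recycled to
#'   \code{""} when absent for a set).
#' @param path output file.
#' @export
writeGMT <- function(sets, groups, path) {
  g <- groups[names(sets)]
  g[is.na(g)] <- ""
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], g[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' One-on-group fold-change matrix
#'
#' Compares each test-group replicate against the mean of the whole
#' control group: entry (g, j) is the log-ratio of gene g in test replicate
#' j minus gene g's mean over all control replicates. Positive values mean
#' higher expression in the test (domesticated) group.
#'
#' @param se gene-level \linkS4class{CrossExperiment}.
#' @param test,control cross-type labels of the test and control groups.
#' @return numeric matrix, genes x test replicates.
#' @export
oneOnGroupFoldChanges <- function(se, test = "DD", control = "WW") {
  M <- SummarizedExperiment::assay(se, "M")
  iT <- crossColumns(se, test); iC <- crossColumns(se, control)
  if (length(iC) < 2L) stop("control group needs at least 2 replicates")
  M[, iT, drop = FALSE] - rowMeans(M[, iC, drop = FALSE])
}

#' Gene-set perturbation test on one fold-change profile
#'
#' Two-sample unequal-variance t-test of the set members' fold changes
#' against all genes' fold changes, in the style of generally applicable
#' gene-set enrichment: direction \code{"up"} uses the one-sided upper p,
#' \code{"down"} the lower, and \code{"two_way"} applies the upper-tail
#' test to absolute fold changes, which detects coordinated changes of
#' mixed sign.
#'
#' @param fc named numeric vector of per-gene fold changes (one
#'   comparison).
#' @param members character vector of member gene ids (must appear in
#'   \code{fc}).
#' @param direction \code{"up"}, \code{"down"} or \code{"two_way"}.
#' @return The p-value; degenerate (zero-variance) input returns 1.
#' @export
gageSetTest <- function(fc, members, direction = c("up", "down", "two_way")) {
  direction <- match.arg(direction)
  members <- intersect(members, names(fc))
  if (length(members) < 2L) return(1)
  x <- fc[members]
  y <- fc
  if (direction == "two_way") {
    x <- abs(x); y <- abs(y)
  }
  if (stats::var(x) + stats::var(y) == 0) return(1)
  alt <- if (direction == "down") "less" else "greater"
  stats::t.test(x, y, alternative = alt, var.equal = FALSE)$p.value
}

#' Combine per-replicate p-values (Stouffer)
#'
#' Probit (Stouffer) combination with equal weights:
#' Z = sum(qnorm(1 - p)) / sqrt(k (1 + (k - 1) rho)), returned as
#' the upper-tail probability of Z. \code{rho} is the common correlation
#' between the replicate z-scores; one-on-group comparisons share the
#' control-group mean, which induces rho = 1 / (n_control + 1), and
#' \code{\link{runEnrichment}} passes that value so the combined p is
#' calibrated under the null. \code{rho = 0} is the classical Stouffer
#' formula. Inputs are clipped to (1e-300, 1 - 1e-16).
#'
#' @param p numeric vector of p-values from the same set/direction across
#'   independent comparisons.
#' @param rho common inter-comparison correlation of the z-scores.
#' @return Combined p-value.
#' @export
combineComparisons <- function(p, rho = 0) {
  if (length(p) == 0L) stop("empty p-value list")
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  k <- length(p)
  z <- stats::qnorm(1 - p)
  Z <- sum(z) / sqrt(k * (1 + (k - 1) * rho))
  min(max(stats::pnorm(Z, lower.tail = FALSE), 1e-300), 1 - 1e-16)
}

#' Gene-set perturbation analysis between stocks
#'
#' Runs the one-on-group comparison for every gene set and direction (up,
#' down, two-way in the domesticated-vs-wild contrast), combines the
#' per-replicate p-values, and BH-adjusts across sets within each
#' direction. Sets belonging to excluded functional groups (default
#' "Human Diseases") are skipped, as are sets with fewer than
#' \code{minSize} or more than \code{maxSize} members present in the
#' matrix. Significance is called at adjusted p <= \code{qThreshold}; the
#' focused two-way list additionally requires combined raw p <=
#' \code{p2dFocus} (configurable to apply to the adjusted p). Essential
#' genes are extracted for significant sets.
#'
#' @param se gene-level \linkS4class{CrossExperiment}.
#' @param geneSets list from \code{\link{readGMT}}.
#' @param qThreshold BH-adjusted significance cutoff.
#' @param p2dFocus focused two-way cutoff.
#' @param focusOn apply \code{p2dFocus} to the \code{"raw"} (default) or
#'   \code{"adjusted"} combined p.
#' @param excludeGroups functional groups to skip.
#' @param minSize,maxSize bounds on members present in the matrix.
#' @param test,control cross-type labels of the contrast.
#' @return data.frame with one row per set x direction: \code{set_id},
#'   \code{functional_group}, \code{direction}, \code{n_members},
#'   \code{mean_stat} (mean member fold change, absolute for two-way),
#'   \code{p_raw} (combined), \code{p_adj}, \code{significant},
#'   \code{focus_2d}, \code{essential_genes} (semicolon-joined).
#' @export
runEnrichment <- function(se, geneSets, qThreshold = 0.1, p2dFocus = 0.02,
                          focusOn = c("raw", "adjusted"),
                          excludeGroups = "Human Diseases",
                          minSize = 10, maxSize = 500,
                          test = "DD", control = "WW") {
  focusOn <- match.arg(focusOn)
  fc <- oneOnGroupFoldChanges(se, test, control)
  rho <- 1 / (length(crossColumns(se, control)) + 1)
  sets <- geneSets$sets
  groups <- geneSets$groups[names(sets)]
  keep <- !(groups %in% excludeGroups)
  sets <- sets[keep]; groups <- groups[keep]
  present <- lapply(sets, intersect, rownames(se))
  size <- vapply(present, length, 1L)
  ok <- size >= minSize & size <= maxSize
  if (!any(ok)) {
    warning("no gene set passes the size filter")
    return(data.frame())
  }
  sets <- sets[ok]; groups <- groups[ok]
  present <- present[ok]; size <- size[ok]
  directions <- c("up", "down", "two_way")
  res <- do.call(rbind, lapply(directions, function(dir) {
    p <- vapply(present, function(mem) {
      pj <- vapply(seq_len(ncol(fc)), function(j) {
        gageSetTest(fc[, j], mem, dir)
      }, 1)
      combineComparisons(pj, rho = rho)
    }, 1)
    stat <- vapply(present, function(mem) {
      x <- fc[mem, , drop = FALSE]
      if (dir == "two_way") mean(abs(x)) else mean(x)
    }, 1)
    data.frame(set_id = names(sets), functional_group = unname(groups),
               direction = dir, n_members = unname(size),
               mean_stat = unname(stat), p_raw = unname(p),
               p_adj = bhAdjust(unname(p)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  res$significant <- res$p_adj <= qThreshold
  pf <- if (focusOn == "raw") res$p_raw else res$p_adj
  res$focus_2d <- res$direction == "two_way" & res$significant &
    pf <= p2dFocus
  res$essential_genes <- ""
  sig <- which(res$significant)
  for (i in sig) {
    ess <- essentialGenes(se, sets[[res$set_id[i]]], test = test,
                          control = control)
    res$essential_genes[i] <- paste(ess, collapse = ";")
  }
  res
}

#' Essential genes of a perturbed set
#'
#' Set members whose mean stock difference deviates from the mean of all
#' genes' differences by more than \code{sdMult} standard deviations of
#' those differences, and whose per-gene Welch t-test (unadjusted) gives
#' p <= \code{pThreshold}.
#'
#' @param se gene-level \linkS4class{CrossExperiment}.
#' @param members character vector of member gene ids.
#' @param sdMult deviation multiple (default 1 SD).
#' @param pThreshold per-gene Welch t cutoff.
#' @param test,control cross-type labels of the contrast.
#' @return Character vector of qualifying member gene ids (sorted).
#' @export
essentialGenes <- function(se, members, sdMult = 1, pThreshold = 0.05,
                           test = "DD", control = "WW") {
  M <- SummarizedExperiment::assay(se, "M")
  iT <- crossColumns(se, test); iC <- crossColumns(se, control)
  wt <- rowWelchT(M, iT, iC)
  d <- wt$meanA - wt$meanB
  thr <- sdMult * stats::sd(d)
  members <- intersect(members, rownames(M))
  idx <- match(members, rownames(M))
  qual <- abs(d[idx] - mean(d)) > thr & wt$p[idx] <= pThreshold
  sort(members[qual])
}

#' Assign a gene's primary function
#'
#' A gene represented in several gene sets is assigned the candidate set
#' with the largest number of member genes present in the analysed gene
#' list; ties go to the lexicographically first set id.
#'
#' @param geneId the gene (must belong to at least one candidate).
#' @param candidateSets named list of member vectors containing the gene.
#' @param geneUniverse character vector: the complete analysed gene list.
#' @return The chosen set id.
#' @export
assignPrimaryFunction <- function(geneId, candidateSets, geneUniverse) {
  candidateSets <- candidateSets[vapply(candidateSets, function(m)
    geneId %in% m, TRUE)]
  if (length(candidateSets) == 0L) {
    stop("gene '", geneId, "' belongs to no candidate set")
  }
  n <- vapply(candidateSets, function(m)
    length(intersect(m, geneUniverse)), 1L)
  ids <- names(candidateSets)
  ids[order(-n, ids)][1L]
}
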