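#' Welch two-sample t-test
#'
#' Unpaired, unequal-variance t-test (Welch-Satterthwaite degrees of
#' freedom), two-sided. Degenerate input where both groups are constant and
#' equal returns t = 0, p = 1 by convention; constant but unequal groups
#' return p = 0.
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @return Named numeric vector \code{c(t=, p=)}.
#' @export
welchT <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (stats::var(a) + stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(c(t = 0, p = 1))
    return(c(t = sign(mean(b) - mean(a)) * Inf, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  c(t = unname(ht$statistic), p = ht$p.value)
}

# vectorized Welch t over matrix rows: columns idxA vs idxB
rowWelchT <- function(M, idxA, idxB) {
  na <- length(idxA); nb <- length(idxB)
  A <- M[, idxA, drop = FALSE]; B <- M[, idxB, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  zero <- se2 == 0
  if (any(zero)) {
    eq <- zero & ma == mb
    t[eq] <- 0; p[eq] <- 1
    ne <- zero & ma != mb
    t[ne] <- sign(ma - mb)[ne] * Inf; p[ne] <- 0
  }
  list(t = t, p = p, meanA = ma, meanB = mb)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (wraps
#' \code{\link[stats]{p.adjust}}).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential expression between the pure stocks
#'
#' Per-gene Welch t-test of the domesticated (DD) against the wild (WW)
#' replicates on the log2-ratio matrix, BH-adjusted, with a linear
#' fold-change filter applied in either direction:
#' significant iff adjusted p <= \code{alpha} and
#' max(FC, 1/FC) >= \code{fcThreshold}, where FC = 2^(mean_D - mean_W) on
#' back-transformed group means.
#'
#' @param se a gene- or probe-level \linkS4class{CrossExperiment} containing
#'   WW and DD columns.
#' @param alpha adjusted-p cutoff.
#' @param fcThreshold linear fold-change cutoff (>= 1).
#' @return data.frame with \code{gene_id}, \code{t}, \code{p_raw},
#'   \code{p_adj}, \code{log2_fc} (domesticated minus wild) and
#'   \code{significant}.
#' @export
deBetweenStocks <- function(se, alpha = 0.05, fcThreshold = 1.25) {
  M <- SummarizedExperiment::assay(se, "M")
  iW <- crossColumns(se, "WW"); iD <- crossColumns(se, "DD")
  if (length(iW) < 2L || length(iD) < 2L) {
    stop("each pure stock needs at least 2 replicate arrays")
  }
  wt <- rowWelchT(M, iD, iW)
  p_adj <- bhAdjust(wt$p)
  log2_fc <- wt$meanA - wt$meanB
  data.frame(
    gene_id = rownames(M),
    t = wt$t,
    p_raw = wt$p,
    p_adj = p_adj,
    log2_fc = log2_fc,
    significant = p_adj <= alpha & abs(log2_fc) >= log2(fcThreshold),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Unequal-variance one-way ANOVA (wraps
#' \code{\link[stats]{oneway.test}}). All groups constant and equal gives
#' p = 1 by convention; a zero-variance group whose mean differs from the
#' rest gives p = 0.
#'
#' @param groups list of numeric vectors, one per group, each of length
#'   >= 2.
#' @return The p-value.
#' @export
welchAnova <- function(groups) {
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("each group needs at least 2 values")
  }
  vars <- vapply(groups, stats::var, 1)
  means <- vapply(groups, mean, 1)
  if (all(vars == 0)) {
    return(if (length(unique(means)) == 1L) 1 else 0)
  }
  if (any(vars == 0)) {
    return(if (length(unique(means)) == 1L) 1 else 0)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  stats::oneway.test(x ~ g, var.equal = FALSE)$p.value
}

# vectorized Welch ANOVA across matrix rows; groups = factor over columns
rowWelchAnova <- function(M, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  idx <- split(seq_len(ncol(M)), groups)
  n <- vapply(idx, length, 1L)
  means <- vars <- matrix(0, nrow(M), k)
  for (g in seq_len(k)) {
    X <- M[, idx[[g]], drop = FALSE]
    means[, g] <- rowMeans(X)
    vars[, g] <- rowSums((X - means[, g])^2) / (n[g] - 1)
  }
  w <- sweep(1 / vars, 2, n, "*")                  # n_g / s_g^2
  U <- rowSums(w)
  xbar <- rowSums(w * means) / U
  Astat <- rowSums(w * (means - xbar)^2) / (k - 1)
  tmp <- sweep((1 - w / U)^2, 2, n - 1, "/")
  Bsum <- rowSums(tmp)
  Fstat <- Astat / (1 + 2 * (k - 2) / (k^2 - 1) * Bsum)
  df2 <- (k^2 - 1) / (3 * Bsum)
  p <- stats::pf(Fstat, k - 1, df2, lower.tail = FALSE)
  degen <- rowSums(vars == 0) > 0
  if (any(degen)) {
    same <- degen &
      apply(means, 1L, function(m) length(unique(m)) == 1L)
    p[degen] <- 0
    p[same] <- 1
  }
  list(p = p, means = means, vars = vars, groups = levels(groups))
}

#' Student-Newman-Keuls post-hoc contrasts
#'
#' Stepwise studentized-range procedure on the ordered group means with the
#' pooled within-group mean square. The widest range is tested first;
#' sub-ranges are tested only while every enclosing range rejects, so the
#' result is closed under enclosure. Unequal group sizes use the
#' Tukey-Kramer form of the range denominator.
#'
#' @param groups named list of numeric vectors (the group labels become
#'   pair labels).
#' @param alphaSnk per-step significance level.
#' @return Character vector of significant pairs, each \code{"A-B"} with
#'   labels in the order given in \code{groups}.
#' @export
snkPosthoc <- function(groups, alphaSnk = 0.05) {
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  n <- vapply(groups, length, 1L)
  if (any(n < 2L)) stop("each group needs at least 2 values")
  means <- vapply(groups, mean, 1)
  vars <- vapply(groups, stats::var, 1)
  dfe <- sum(n - 1L)
  mse <- sum((n - 1L) * vars) / dfe
  if (mse == 0) {
    mse <- .Machine$double.eps
  }
  k <- length(groups)
  ord <- order(means)
  sig <- matrix(FALSE, k, k)   # over ordered positions i < j
  reject <- function(i, j) {
    r <- j - i + 1L
    ii <- ord[i]; jj <- ord[j]
    q <- (means[jj] - means[ii]) /
      sqrt(mse / 2 * (1 / n[ii] + 1 / n[jj]))
    stats::ptukey(q, r, dfe, lower.tail = FALSE) <= alphaSnk
  }
  for (r in seq(k, 2L)) {
    for (i in seq_len(k - r + 1L)) {
      j <- i + r - 1L
      open <- if (r == k) TRUE else {
        up <- c(if (i > 1L) sig[i - 1L, j], if (j < k) sig[i, j + 1L])
        all(up)
      }
      sig[i, j] <- open && reject(i, j)
    }
  }
  pairs <- character()
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      if (sig[i, j]) {
        ab <- sort(match(c(labels[ord[i]], labels[ord[j]]), labels))
        pairs <- c(pairs, paste(labels[ab], collapse = "-"))
      }
    }
  }
  sort(unique(pairs))
}

#' Welch ANOVA across the four cross types with SNK follow-up
#'
#' Runs the unequal-variance one-way ANOVA per gene across all cross-type
#' groups, BH-adjusts across genes, and runs the SNK post-hoc only for
#' genes passing \code{fdrThreshold} (post-hoc is gene-local and not
#' adjusted across genes).
#'
#' @param se a gene-level \linkS4class{CrossExperiment}.
#' @param fdrThreshold BH-adjusted ANOVA p cutoff gating the post-hoc.
#' @param alphaSnk SNK per-step level.
#' @return data.frame with \code{gene_id}, \code{anova_p_raw},
#'   \code{anova_p_adj} and \code{significant_pairs} (semicolon-joined, e.g.
#'   \code{"WW-DW;WD-DD"}; empty when not gated in or no pair rejects).
#' @export
anovaPosthoc <- function(se, fdrThreshold = 0.10, alphaSnk = 0.05) {
  M <- SummarizedExperiment::assay(se, "M")
  ct <- crossType(se)
  res <- rowWelchAnova(M, ct)
  p_adj <- bhAdjust(res$p)
  pairs <- character(nrow(M))
  gated <- which(p_adj <= fdrThreshold)
  idx <- split(seq_len(ncol(M)), ct)[CROSS_TYPES[CROSS_TYPES %in% ct]]
  for (i in gated) {
    groups <- lapply(idx, function(cols) M[i, cols])
    pairs[i] <- paste(snkPosthoc(groups, alphaSnk), collapse = ";")
  }
  data.frame(
    gene_id = rownames(M),
    anova_p_raw = res$p,
    anova_p_adj = p_adj,
    significant_pairs = pairs,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
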