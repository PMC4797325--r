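MODE_LEVELS <- c("additive", "wild_dominant", "domesticated_dominant",
                 "over_dominant", "undefined")
CLASS_LEVELS <- c("wild_overdominant", "wild_dominant", "additive",
                  "domesticated_dominant", "domesticated_overdominant")

#' Additivity and dominance of hybrid expression
#'
#' For group means on the normalised-intensity (log2-ratio) scale,
#' additivity is alpha = (W - D) / 2 and dominance is
#' delta = (W + D) / 2 - hybrid: a hybrid at mid-parent expression has
#' delta = 0; a hybrid matching the wild parent has delta/alpha = -1 and one
#' matching the domesticated parent has delta/alpha = +1. The ratio is
#' undefined (NA) when alpha = 0.
#'
#' @param W,D,H numeric vectors of pure-wild, pure-domesticated and hybrid
#'   group means.
#' @return data.frame with \code{alpha}, \code{delta}, \code{ratio}.
#' @export
additivityDominance <- function(W, D, H) {
  alpha <- (W - D) / 2
  delta <- (W + D) / 2 - H
  ratio <- ifelse(alpha == 0, NA_real_, delta / alpha)
  if (any(alpha == 0 & delta != 0)) {
    message(sum(alpha == 0 & delta != 0),
            " gene(s) with alpha = 0 but nonzero dominance; ",
            "ratio left undefined")
  }
  data.frame(alpha = alpha, delta = delta, ratio = ratio)
}

#' Classify inheritance mode from delta/alpha
#'
#' Interval rule: additive for -0.5 < ratio < 0.5; wild-dominant for
#' -1.5 < ratio <= -0.5; domesticated-dominant for 0.5 <= ratio < 1.5;
#' over-dominant for |ratio| >= 1.5. The measure-zero boundaries (excluded
#' by the strict inequalities of the rule) are assigned deterministically:
#' +/-0.5 to the dominant classes and +/-1.5 to over-dominance. Undefined
#' ratios (NA) classify as \code{"undefined"}.
#'
#' @param ratio numeric vector of delta/alpha values.
#' @return Character vector over \code{additive}, \code{wild_dominant},
#'   \code{domesticated_dominant}, \code{over_dominant}, \code{undefined}.
#' @export
classifyMode <- function(ratio) {
  mode <- rep("undefined", length(ratio))
  def <- !is.na(ratio)
  r <- ratio[def]
  m <- character(length(r))
  m[abs(r) < 0.5] <- "additive"
  m[r <= -0.5 & r > -1.5] <- "wild_dominant"
  m[r >= 0.5 & r < 1.5] <- "domesticated_dominant"
  m[abs(r) >= 1.5] <- "over_dominant"
  mode[def] <- m
  mode
}

parsePairs <- function(s) {
  if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1L]]
}

canonicalPair <- function(a, b) {
  ab <- c(a, b)[order(match(c(a, b), CROSS_TYPES))]
  paste(ab, collapse = "-")
}

#' Exclude transcripts differing only between the pure crosses
#'
#' A transcript whose only significant post-hoc contrast is WW vs DD says
#' nothing about hybrid inheritance and is excluded from parental-effect
#' categorization.
#'
#' @param posthoc data.frame from \code{\link{anovaPosthoc}}.
#' @return list with \code{kept} and \code{excluded} subsets of
#'   \code{posthoc}.
#' @export
excludePureOnly <- function(posthoc) {
  pureOnly <- vapply(posthoc$significant_pairs, function(s) {
    pr <- parsePairs(s)
    length(pr) > 0L && all(pr == "DD-WW" | pr == "WW-DD")
  }, TRUE, USE.NAMES = FALSE)
  list(kept = posthoc[!pureOnly, , drop = FALSE],
       excluded = posthoc[pureOnly, , drop = FALSE])
}

MATERNAL_PAIRS <- c("WW-DW", "WD-DD")
PATERNAL_PAIRS <- c("WW-WD", "DW-DD")

#' Categorize parental effects from post-hoc contrasts
#'
#' Default \code{"line"} scheme uses line-sharing logic: a contrast that
#' changes the maternal line while sharing the paternal line (WW vs DW, or
#' WD vs DD) is evidence of a maternal effect; a contrast sharing the
#' mother but changing the father (WW vs WD, or DW vs DD) of a paternal
#' effect; both kinds present make the gene \code{"parental"}; only the
#' reciprocal-hybrid contrast (WD vs DW) makes it \code{"hybrid_only"}; no
#' informative contrast leaves it \code{"uncategorized"}. The
#' \code{"literal"} scheme reproduces the published category lists
#' verbatim (any contrast of WW against DW/DD/WD counts as both maternal
#' and paternal evidence; the lists are identical, so genes with such a
#' contrast come out \code{"parental"} unless only one list is matched).
#'
#' @param pairs character vector of significant pairs (e.g.
#'   \code{c("WW-DW")}) or a semicolon-joined string.
#' @param scheme \code{"line"} (default) or \code{"literal"}.
#' @return One of \code{"maternal"}, \code{"paternal"}, \code{"parental"},
#'   \code{"hybrid_only"}, \code{"uncategorized"}.
#' @export
categorizeParentalEffect <- function(pairs, scheme = c("line", "literal")) {
  scheme <- match.arg(scheme)
  if (length(pairs) == 1L && grepl(";", pairs)) pairs <- parsePairs(pairs)
  pairs <- vapply(pairs, function(p) {
    ab <- strsplit(p, "-", fixed = TRUE)[[1L]]
    canonicalPair(ab[1L], ab[2L])
  }, "", USE.NAMES = FALSE)
  if (length(pairs) == 0L) return("uncategorized")
  if (scheme == "line") {
    mat <- any(pairs %in% MATERNAL_PAIRS)
    pat <- any(pairs %in% PATERNAL_PAIRS)
  } else {
    lit <- c("WW-DW", "WW-DD", "WW-WD")
    mat <- any(pairs %in% lit)
    pat <- any(pairs %in% lit)
  }
  if (mat && pat) return("parental")
  if (mat) return("maternal")
  if (pat) return("paternal")
  if (all(pairs == "WD-DW")) return("hybrid_only")
  "uncategorized"
}

#' Per-gene, per-hybrid heritability calls
#'
#' For every gene retained by the ANOVA/SNK gate (pure-cross-only genes
#' excluded), computes alpha, delta and delta/alpha against each hybrid's
#' group mean, classifies the inheritance mode, and attaches the
#' parental-effect category derived from the gene's significant contrasts.
#'
#' @param se gene-level \linkS4class{CrossExperiment} (all four cross
#'   types).
#' @param posthoc data.frame from \code{\link{anovaPosthoc}}.
#' @param scheme parental-effect scheme, see
#'   \code{\link{categorizeParentalEffect}}.
#' @param onlySignificant keep only genes with a nonempty significant pair
#'   set (default TRUE, mirroring the published workflow).
#' @return data.frame with one row per gene x hybrid: \code{gene_id},
#'   \code{hybrid} (WD or DW), \code{alpha}, \code{delta}, \code{ratio},
#'   \code{mode}, \code{effect_category}.
#' @export
heritabilityCalls <- function(se, posthoc, scheme = c("line", "literal"),
                              onlySignificant = TRUE) {
  scheme <- match.arg(scheme)
  kept <- excludePureOnly(posthoc)$kept
  if (onlySignificant) {
    kept <- kept[nzchar(kept$significant_pairs), , drop = FALSE]
  }
  M <- SummarizedExperiment::assay(se, "M")
  kept <- kept[kept$gene_id %in% rownames(M), , drop = FALSE]
  means <- sapply(CROSS_TYPES, function(ct)
    rowMeans(M[kept$gene_id, crossColumns(se, ct), drop = FALSE]))
  if (nrow(kept) == 1L) means <- matrix(means, 1L,
                                        dimnames = list(NULL, CROSS_TYPES))
  cat_per_gene <- vapply(kept$significant_pairs, categorizeParentalEffect,
                         "", scheme = scheme, USE.NAMES = FALSE)
  out <- do.call(rbind, lapply(c("WD", "DW"), function(h) {
    ad <- additivityDominance(means[, "WW"], means[, "DD"], means[, h])
    data.frame(gene_id = kept$gene_id, hybrid = h, ad,
               mode = classifyMode(ad$ratio),
               effect_category = cat_per_gene,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Per-hybrid inheritance-class percentage table
#'
#' Summarizes heritability calls into the five-class layout (wild
#' over-dominant, wild dominant, additive, domesticated dominant,
#' domesticated over-dominant); over-dominant calls are split by the sign
#' of delta/alpha (negative = wild side). Percentages are over genes with a
#' defined mode and sum to 100; genes with undefined ratio are counted in
#' their own column and never silently dropped. Genes with |ratio| above
#' the plotting cap stay in the table.
#'
#' @param calls data.frame from \code{\link{heritabilityCalls}}.
#' @return data.frame, one row per hybrid: \code{hybrid},
#'   \code{n_genes}, percentage columns for the five classes, and
#'   \code{n_undefined}.
#' @export
heritabilityTable <- function(calls) {
  if (nrow(calls) == 0L) {
    warning("no classified genes; returning empty table")
    return(data.frame(hybrid = character(), n_genes = integer()))
  }
  do.call(rbind, lapply(unique(calls$hybrid), function(h) {
    ch <- calls[calls$hybrid == h, , drop = FALSE]
    cls <- ch$mode
    cls[cls == "over_dominant" & ch$ratio < 0] <- "wild_overdominant"
    cls[cls == "over_dominant"] <- "domesticated_overdominant"
    def <- cls != "undefined"
    tab <- table(factor(cls[def], levels = CLASS_LEVELS))
    pct <- as.numeric(tab) / max(sum(def), 1L) * 100
    out <- data.frame(hybrid = h, n_genes = sum(def),
                      rbind(pct), n_undefined = sum(!def),
                      stringsAsFactors = FALSE, row.names = NULL)
    colnames(out)[3:7] <- paste0(CLASS_LEVELS, "_pct")
    out
  }))
}
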