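#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

CROSS_TYPES <- c("WW", "WD", "DW", "DD")

#' Raw two-colour array batch
#'
#' Container for background-subtracted channel intensities and vendor QC
#' flags for a batch of common-reference two-colour arrays. Rows are probes,
#' columns are arrays. \code{cy3} holds the test-sample channel, \code{cy5}
#' the common reference channel. Flags mirror the feature-extraction
#' software's per-feature calls: saturation, probe-population outlier, and
#' the two-sided background t-test ("positive and significant").
#'
#' @slot cy3,cy5 numeric matrices of non-negative intensities (probes x arrays).
#' @slot saturated,outlier,aboveBackground logical matrices, same dimensions.
#' @slot probeData \code{DataFrame} with columns \code{probe_id} (unique) and
#'   \code{is_control}.
#' @slot sampleData \code{DataFrame} with columns \code{array_id},
#'   \code{cross_type} (one of WW, WD, DW, DD; WD = wild dam x domesticated
#'   sire, DW the reciprocal), \code{replicate} and \code{slide_id}.
#'
#' @exportClass TwoColourArraySet
setClass("TwoColourArraySet",
  representation(
    cy3 = "matrix",
    cy5 = "matrix",
    saturated = "matrix",
    outlier = "matrix",
    aboveBackground = "matrix",
    probeData = "DataFrame",
    sampleData = "DataFrame"
  )
)

setValidity("TwoColourArraySet", function(object) {
  msg <- character()
  d <- dim(object@cy3)
  for (sl in c("cy5", "saturated", "outlier", "aboveBackground")) {
    if (!identical(dim(slot(object, sl)), d)) {
      msg <- c(msg, sprintf("dim(%s) does not match dim(cy3)", sl))
    }
  }
  if (nrow(object@probeData) != d[1L]) {
    msg <- c(msg, "probeData rows must match probe dimension")
  }
  if (nrow(object@sampleData) != d[2L]) {
    msg <- c(msg, "sampleData rows must match array dimension")
  }
  if (!all(c("probe_id", "is_control") %in% colnames(object@probeData))) {
    msg <- c(msg, "probeData needs columns probe_id, is_control")
  } else if (anyDuplicated(object@probeData$probe_id)) {
    msg <- c(msg, "probe ids must be unique")
  }
  need <- c("array_id", "cross_type", "replicate", "slide_id")
  if (!all(need %in% colnames(object@sampleData))) {
    msg <- c(msg, paste("sampleData needs columns",
                        paste(need, collapse = ", ")))
  } else {
    ct <- as.character(object@sampleData$cross_type)
    if (!all(ct %in% CROSS_TYPES)) {
      msg <- c(msg, sprintf("unknown cross_type label(s): %s",
                            paste(unique(setdiff(ct, CROSS_TYPES)),
                                  collapse = ", ")))
    }
    key <- paste(ct, object@sampleData$replicate)
    if (anyDuplicated(key)) {
      msg <- c(msg, "(cross_type, replicate) pairs must be unique")
    }
  }
  if (any(object@cy3 < 0, na.rm = TRUE) || any(object@cy5 < 0, na.rm = TRUE)) {
    msg <- c(msg, "intensities must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TwoColourArraySet
#'
#' @param cy3,cy5 numeric matrices (probes x arrays) of non-negative
#'   background-subtracted intensities; test sample in cy3, common reference
#'   in cy5.
#' @param saturated,outlier,aboveBackground logical matrices of per-feature
#'   QC flags, same dimensions. Defaults: nothing saturated or outlying,
#'   everything above background.
#' @param probeData data.frame/DataFrame with \code{probe_id},
#'   \code{is_control}.
#' @param sampleData data.frame/DataFrame with \code{array_id},
#'   \code{cross_type}, \code{replicate}, \code{slide_id}.
#' @return A \linkS4class{TwoColourArraySet}.
#' @export
TwoColourArraySet <- function(cy3, cy5, probeData, sampleData,
                              saturated = NULL, outlier = NULL,
                              aboveBackground = NULL) {
  cy3 <- as.matrix(cy3)
  cy5 <- as.matrix(cy5)
  lf <- function(x, default) {
    if (is.null(x)) {
      matrix(default, nrow(cy3), ncol(cy3))
    } else {
      m <- as.matrix(x)
      storage.mode(m) <- "logical"
      m
    }
  }
  probeData <- DataFrame(probeData)
  sampleData <- DataFrame(sampleData)
  dimnames(cy3) <- dimnames(cy5) <-
    list(as.character(probeData$probe_id),
         as.character(sampleData$array_id))
  new("TwoColourArraySet",
      cy3 = cy3, cy5 = cy5,
      saturated = lf(saturated, FALSE),
      outlier = lf(outlier, FALSE),
      aboveBackground = lf(aboveBackground, TRUE),
      probeData = probeData, sampleData = sampleData)
}

#' Reciprocal-cross expression experiment
#'
#' A \linkS4class{SummarizedExperiment} holding the normalized log2(cy3/cy5)
#' matrix in assay \code{"M"}, with column metadata describing the cross
#' design (\code{cross_type} in WW/WD/DW/DD and \code{replicate}). Rows are
#' probes, or genes after collapsing.
#'
#' @exportClass CrossExperiment
setClass("CrossExperiment", contains = "SummarizedExperiment")

setValidity("CrossExperiment", function(object) {
  msg <- character()
  if (!"M" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'M' (log2 ratios) is required")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("cross_type", "replicate") %in% colnames(cd))) {
    msg <- c(msg, "colData needs cross_type and replicate")
  } else if (!all(as.character(cd$cross_type) %in% CROSS_TYPES)) {
    msg <- c(msg, "cross_type must be one of WW, WD, DW, DD")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msg <- c(msg, "row names must be present and unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CrossExperiment
#'
#' @param M numeric matrix of log2 ratios, rows = probes or genes (named),
#'   columns = arrays.
#' @param sampleData data.frame/DataFrame aligned to columns with
#'   \code{array_id}, \code{cross_type}, \code{replicate} (and optionally
#'   \code{slide_id}).
#' @param rowData optional data.frame/DataFrame of row metadata.
#' @return A \linkS4class{CrossExperiment}.
#' @export
CrossExperiment <- function(M, sampleData, rowData = NULL) {
  M <- as.matrix(M)
  sampleData <- DataFrame(sampleData)
  if (is.null(colnames(M))) colnames(M) <- as.character(sampleData$array_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(M = M),
    colData = sampleData,
    rowData = if (is.null(rowData)) NULL else DataFrame(rowData)
  )
  new("CrossExperiment", se)
}
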