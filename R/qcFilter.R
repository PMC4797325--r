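#' Probe quality filter
#'
#' Applies the study-style retention rule to a batch of arrays. A probe is
#' removed globally if it is a technical control, or flagged saturated or a
#' probe-population outlier on any array. A probe is retained only if it is
#' "positive and significant" against background on at least
#' \code{fracThreshold} of the arrays (rounded up) in at least
#' \code{minGroups} cross-type groups; with 6 arrays per group and the 0.75
#' default that is at least 5 of 6 arrays in any two groups.
#'
#' @param object a \linkS4class{TwoColourArraySet}.
#' @param fracThreshold required within-group fraction of above-background
#'   arrays, in (0, 1].
#' @param minGroups number of cross-type groups that must pass.
#' @return Sorted character vector of retained probe ids.
#' @rdname qcFilter
#' @export
setMethod("qcFilter", "TwoColourArraySet",
          function(object, fracThreshold = 0.75, minGroups = 2) {
  if (!is.numeric(fracThreshold) || length(fracThreshold) != 1L ||
      fracThreshold <= 0 || fracThreshold > 1) {
    stop("fracThreshold must be a single value in (0, 1]")
  }
  bad <- object@probeData$is_control |
    rowSums(object@saturated) > 0L |
    rowSums(object@outlier) > 0L
  ct <- crossType(object)
  groups <- unique(ct)
  passes <- matrix(FALSE, nrow(object@cy3), length(groups))
  for (g in seq_along(groups)) {
    cols <- which(ct == groups[g])
    needed <- ceiling(fracThreshold * length(cols))
    passes[, g] <-
      rowSums(object@aboveBackground[, cols, drop = FALSE]) >= needed
  }
  keep <- !bad & rowSums(passes) >= minGroups
  sort(as.character(object@probeData$probe_id[keep]))
})
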