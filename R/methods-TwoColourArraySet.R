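#' Accessors for array containers
#'
#' @param object a \linkS4class{TwoColourArraySet} or
#'   \linkS4class{CrossExperiment}.
#' @return \code{cy3}/\code{cy5}: intensity matrices. \code{probeData},
#'   \code{sampleData}: the metadata \code{DataFrame}s. \code{crossType}:
#'   character vector of per-array cross labels.
#' @name accessors
NULL

#' @rdname accessors
setMethod("cy3", "TwoColourArraySet", function(object) object@cy3)

#' @rdname accessors
setMethod("cy5", "TwoColourArraySet", function(object) object@cy5)

#' @rdname accessors
setMethod("probeData", "TwoColourArraySet", function(object) object@probeData)

#' @rdname accessors
setMethod("sampleData", "TwoColourArraySet", function(object) object@sampleData)

#' @rdname accessors
setMethod("crossType", "TwoColourArraySet",
          function(object) as.character(object@sampleData$cross_type))

#' @rdname accessors
setMethod("crossType", "CrossExperiment",
          function(object)
            as.character(SummarizedExperiment::colData(object)$cross_type))

setMethod("show", "TwoColourArraySet", function(object) {
  ct <- table(crossType(object))
  cat("TwoColourArraySet with", nrow(object@cy3), "probes x",
      ncol(object@cy3), "arrays\n")
  cat("  controls:", sum(object@probeData$is_control), "probes\n")
  cat("  arrays per cross type:",
      paste(sprintf("%s=%d", names(ct), as.integer(ct)), collapse = " "),
      "\n")
  invisible(NULL)
})

setMethod("dim", "TwoColourArraySet", function(x) dim(x@cy3))

#' Subset a TwoColourArraySet
#'
#' @param x a \linkS4class{TwoColourArraySet}.
#' @param i probe (row) index. @param j array (column) index.
#' @param ... ignored. @param drop ignored.
#' @export
setMethod("[", "TwoColourArraySet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@cy3))
  if (missing(j)) j <- seq_len(ncol(x@cy3))
  initialize(x,
    cy3 = x@cy3[i, j, drop = FALSE],
    cy5 = x@cy5[i, j, drop = FALSE],
    saturated = x@saturated[i, j, drop = FALSE],
    outlier = x@outlier[i, j, drop = FALSE],
    aboveBackground = x@aboveBackground[i, j, drop = FALSE],
    probeData = x@probeData[i, , drop = FALSE],
    sampleData = x@sampleData[j, , drop = FALSE])
})

#' Floor channel intensities
#'
#' Raises all intensities below \code{floor} (default 1) to \code{floor}, so
#' that log ratios are always finite. Values already at or above the floor
#' are unchanged.
#'
#' @param object a \linkS4class{TwoColourArraySet} or a numeric vector/matrix.
#' @param floor minimum retained intensity.
#' @return An object of the same class with both channels floored.
#' @name floorIntensities
#' @examples
#' floorIntensities(c(0.2, 1, 57.3))
NULL

#' @rdname floorIntensities
setMethod("floorIntensities", "TwoColourArraySet", function(object, floor = 1) {
  object@cy3 <- pmax(object@cy3, floor)
  object@cy5 <- pmax(object@cy5, floor)
  object
})

#' @rdname floorIntensities
setMethod("floorIntensities", "numeric", function(object, floor = 1) {
  pmax(object, floor)
})

#' @rdname floorIntensities
setMethod("floorIntensities", "matrix", function(object, floor = 1) {
  pmax(object, floor)
})

# columns of a CrossExperiment belonging to one cross type
crossColumns <- function(se, type) {
  which(crossType(se) == type)
}
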