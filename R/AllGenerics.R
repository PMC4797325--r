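#' @rdname floorIntensities
#' @export
setGeneric("floorIntensities", function(object, floor = 1)
  standardGeneric("floorIntensities"))

#' @rdname accessors
#' @export
setGeneric("cy3", function(object) standardGeneric("cy3"))

#' @rdname accessors
#' @export
setGeneric("cy5", function(object) standardGeneric("cy5"))

#' @rdname accessors
#' @export
setGeneric("probeData", function(object) standardGeneric("probeData"))

#' @rdname accessors
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @rdname accessors
#' @export
setGeneric("crossType", function(object) standardGeneric("crossType"))

#' @rdname lowessNormalize
#' @export
setGeneric("lowessNormalize", function(object, span = 0.3, iterations = 3)
  standardGeneric("lowessNormalize"))

#' @rdname qcFilter
#' @export
setGeneric("qcFilter",
  function(object, fracThreshold = 0.75, minGroups = 2)
    standardGeneric("qcFilter"))
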