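#' Within-array Lowess (MA) normalization
#'
#' For each array, fits a locally weighted regression (tricube weights,
#' robustness iterations; \code{\link[stats]{lowess}}) of
#' M = log2(cy3/cy5) on A = 0.5*log2(cy3*cy5) over the non-control probes
#' and subtracts the fitted intensity-dependent trend, removing dye bias.
#' Control probes are dropped from the output: they never enter downstream
#' matrices.
#'
#' @param object a floored \linkS4class{TwoColourArraySet}; intensities
#'   below 1 are floored defensively (flooring is idempotent).
#' @param span lowess span (fraction of probes in each local window).
#' @param iterations robustifying iterations.
#' @return A \linkS4class{CrossExperiment} of trend-corrected M values over
#'   the non-control probes.
#' @rdname lowessNormalize
#' @export
setMethod("lowessNormalize", "TwoColourArraySet",
          function(object, span = 0.3, iterations = 3) {
  stopifnot(span > 0, span <= 1)
  object <- floorIntensities(object)
  keep <- !object@probeData$is_control
  if (sum(keep) < 10L) {
    stop("fewer than 10 non-control probes; cannot fit a Lowess trend")
  }
  cy3 <- object@cy3[keep, , drop = FALSE]
  cy5 <- object@cy5[keep, , drop = FALSE]
  M <- log2(cy3) - log2(cy5)
  A <- 0.5 * (log2(cy3) + log2(cy5))
  for (j in seq_len(ncol(M))) {
    M[, j] <- M[, j] - lowessTrend(A[, j], M[, j], span, iterations)
  }
  CrossExperiment(
    M = M,
    sampleData = object@sampleData,
    rowData = object@probeData[keep, , drop = FALSE]
  )
})

# fitted lowess trend of m on a, evaluated at each a
lowessTrend <- function(a, m, span, iterations) {
  if (length(unique(a)) < 2L) {
    return(rep(mean(m), length(a)))
  }
  fit <- stats::lowess(a, m, f = span, iter = iterations)
  stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
}
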