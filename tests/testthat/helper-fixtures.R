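# in-code fixture builders shared across test files

# sample sheet for nRep arrays per cross type
makeSamples <- function(nRep = 6) {
  ct <- rep(c("WW", "WD", "DW", "DD"), each = nRep)
  data.frame(array_id = sprintf("%s_r%02d", ct, rep(seq_len(nRep), 4)),
             cross_type = ct, replicate = rep(seq_len(nRep), 4),
             slide_id = sprintf("s%02d", seq_along(ct)),
             stringsAsFactors = FALSE)
}

# CrossExperiment from a matrix of log-ratios (24 columns by default)
makeCE <- function(M, nRep = ncol(M) / 4, samples = makeSamples(nRep)) {
  rownames(M) <- rownames(M) %||% sprintf("g%04d", seq_len(nrow(M)))
  CrossExperiment(M, samples)
}

# CrossExperiment with WW and DD groups only
makeCE2 <- function(M, nRep = ncol(M) / 2) {
  ct <- rep(c("WW", "DD"), each = nRep)
  samples <- data.frame(
    array_id = sprintf("%s_r%02d", ct, rep(seq_len(nRep), 2)),
    cross_type = ct, replicate = rep(seq_len(nRep), 2),
    slide_id = sprintf("s%02d", seq_along(ct)), stringsAsFactors = FALSE)
  rownames(M) <- rownames(M) %||% sprintf("g%04d", seq_len(nrow(M)))
  CrossExperiment(M, samples)
}

# single-array TwoColourArraySet from planted M and A values
makeOneArray <- function(M, A, id = "WW_r01") {
  TwoColourArraySet(
    cy3 = matrix(2^(A + M / 2), ncol = 1),
    cy5 = matrix(2^(A - M / 2), ncol = 1),
    probeData = data.frame(probe_id = sprintf("p%06d", seq_along(M)),
                           is_control = FALSE, stringsAsFactors = FALSE),
    sampleData = data.frame(array_id = id, cross_type = "WW",
                            replicate = 1, slide_id = "s01",
                            stringsAsFactors = FALSE))
}

# batch whose aboveBackground flags follow a per-probe, per-group pattern:
# pattern[probe, group] = number of arrays in that group flagged above
# background (groups ordered WW, WD, DW, DD)
makeFlagBatch <- function(pattern, nRep = 6, isControl = NULL,
                          saturated = NULL, outlier = NULL) {
  nP <- nrow(pattern)
  samples <- makeSamples(nRep)
  nA <- nrow(samples)
  above <- matrix(FALSE, nP, nA)
  for (g in 1:4) {
    cols <- (g - 1) * nRep + seq_len(nRep)
    for (p in seq_len(nP)) {
      above[p, cols[seq_len(pattern[p, g])]] <- TRUE
    }
  }
  TwoColourArraySet(
    cy3 = matrix(100, nP, nA), cy5 = matrix(100, nP, nA),
    aboveBackground = above,
    saturated = saturated, outlier = outlier,
    probeData = data.frame(
      probe_id = sprintf("p%03d", seq_len(nP)),
      is_control = isControl %||% rep(FALSE, nP),
      stringsAsFactors = FALSE),
    sampleData = samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
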