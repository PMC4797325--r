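FEATURE_COLUMNS <- c("probe_id", "cy3", "cy5", "is_control",
                     "flag_saturated", "flag_outlier",
                     "flag_above_background")

#' Read per-array feature tables and a sample sheet
#'
#' Reads one tab-delimited feature table per array (columns \code{probe_id},
#' \code{cy3}, \code{cy5}, \code{is_control}, \code{flag_saturated},
#' \code{flag_outlier}, \code{flag_above_background}; header mandatory) and a
#' sample sheet assigning each array to a cross type and replicate. All
#' arrays must share one probe universe; rows are aligned by \code{probe_id}.
#' Missing flag columns default to a passing flag, with a warning.
#'
#' @param sampleSheet path to a tab-delimited sample sheet with columns
#'   \code{array_id}, \code{file}, \code{cross_type} (WW/WD/DW/DD),
#'   \code{replicate}, \code{slide_id}.
#' @param dir directory against which relative \code{file} entries are
#'   resolved; defaults to the sample sheet's directory.
#' @return A \linkS4class{TwoColourArraySet}.
#' @export
readFeatureTables <- function(sampleSheet, dir = dirname(sampleSheet)) {
  sheet <- utils::read.delim(sampleSheet, stringsAsFactors = FALSE)
  need <- c("array_id", "file", "cross_type", "replicate", "slide_id")
  if (!all(need %in% colnames(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(sheet$cross_type), CROSS_TYPES)
  if (length(bad)) {
    stop("unknown cross_type label(s) in sample sheet: ",
         paste(bad, collapse = ", "))
  }
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", sheet$file), sheet$file,
                  file.path(dir, sheet$file))
  tabs <- vector("list", nrow(sheet))
  for (k in seq_len(nrow(sheet))) {
    if (!file.exists(paths[k])) {
      stop("feature file for array '", sheet$array_id[k], "' not found: ",
           paths[k])
    }
    tab <- utils::read.delim(paths[k], stringsAsFactors = FALSE)
    if (!"probe_id" %in% colnames(tab) ||
        !all(c("cy3", "cy5") %in% colnames(tab))) {
      stop("array '", sheet$array_id[k],
           "': feature table needs probe_id, cy3, cy5 columns")
    }
    missing <- setdiff(FEATURE_COLUMNS, colnames(tab))
    if (length(missing)) {
      warning("array '", sheet$array_id[k], "': missing column(s) ",
              paste(missing, collapse = ", "),
              "; defaulting to passing flags")
      for (m in missing) {
        tab[[m]] <- if (m == "flag_above_background") TRUE else FALSE
      }
    }
    tabs[[k]] <- tab
  }
  universe <- tabs[[1L]]$probe_id
  if (anyDuplicated(universe)) {
    stop("array '", sheet$array_id[1L], "': duplicated probe ids")
  }
  for (k in seq_along(tabs)[-1L]) {
    ids <- tabs[[k]]$probe_id
    if (!setequal(ids, universe) || length(ids) != length(universe)) {
      offending <- c(setdiff(universe, ids), setdiff(ids, universe))
      stop("array '", sheet$array_id[k],
           "' does not share the common probe universe; mismatched probes: ",
           paste(utils::head(offending, 5L), collapse = ", "))
    }
    tabs[[k]] <- tabs[[k]][match(universe, ids), , drop = FALSE]
  }
  pull <- function(col) {
    do.call(cbind, lapply(tabs, function(t) t[[col]]))
  }
  TwoColourArraySet(
    cy3 = pull("cy3"), cy5 = pull("cy5"),
    saturated = pull("flag_saturated"),
    outlier = pull("flag_outlier"),
    aboveBackground = pull("flag_above_background"),
    probeData = data.frame(
      probe_id = universe,
      is_control = as.logical(tabs[[1L]]$is_control),
      stringsAsFactors = FALSE),
    sampleData = sheet[, need, drop = FALSE]
  )
}

#' Write the log-ratio matrix of a CrossExperiment
#'
#' Tab-delimited text, probes/genes in rows, array ids as column headers.
#'
#' @param se a \linkS4class{CrossExperiment}.
#' @param path output file.
#' @export
writeExpressionMatrix <- function(se, path) {
  M <- SummarizedExperiment::assay(se, "M")
  out <- data.frame(id = rownames(M), M, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
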