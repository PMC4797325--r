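#' Read a probe annotation table
#'
#' Tab-delimited with columns \code{probe_id}, \code{gene_id}, \code{ko_id};
#' empty strings mark missing annotations.
#'
#' @param path annotation file.
#' @return data.frame with character columns, one row per probe.
#' @export
readAnnotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("probe_id", "gene_id", "ko_id")
  if (!all(need %in% colnames(ann))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ann$probe_id)) {
    stop("probe_id must be unique in the annotation table")
  }
  ann[need]
}

annotationKey <- function(ann) {
  gene <- ifelse(is.na(ann$gene_id), "", ann$gene_id)
  ko <- ifelse(is.na(ann$ko_id), "", ann$ko_id)
  ifelse(nzchar(gene), gene, ko)
}

#' Drop probes without gene annotation
#'
#' Keeps only rows whose probe carries a gene and/or KEGG Orthology
#' annotation; probes absent from the annotation table are treated as
#' unannotated (with a message).
#'
#' @param se a probe-level \linkS4class{CrossExperiment}.
#' @param annotation data.frame from \code{\link{readAnnotation}}.
#' @return The subsetted \linkS4class{CrossExperiment}.
#' @export
dropUnannotated <- function(se, annotation) {
  key <- annotationKey(annotation)[match(rownames(se), annotation$probe_id)]
  unknown <- is.na(key)
  if (any(unknown)) {
    message(sum(unknown), " probe(s) absent from the annotation table; ",
            "treated as unannotated")
    key[unknown] <- ""
  }
  se[nzchar(key), ]
}

#' Collapse probes to one representative per gene
#'
#' Where a gene is covered by several probes, keeps the probe with the
#' lowest p-value from the test the downstream comparison will use; ties are
#' broken lexicographically by probe id. Genes are keyed by \code{gene_id},
#' falling back to \code{ko_id} for probes with only a KEGG annotation.
#'
#' @param se an annotated probe-level \linkS4class{CrossExperiment}.
#' @param annotation data.frame from \code{\link{readAnnotation}}.
#' @param pvalues numeric vector of per-probe p-values named by probe id,
#'   covering every row of \code{se}.
#' @return A gene-level \linkS4class{CrossExperiment}; row names are gene
#'   ids, \code{rowData} records the chosen probe and its p-value.
#' @export
collapseToGenes <- function(se, annotation, pvalues) {
  if (is.null(names(pvalues)) || !all(rownames(se) %in% names(pvalues))) {
    stop("pvalues must be named and cover every probe in the matrix")
  }
  key <- annotationKey(annotation)[match(rownames(se), annotation$probe_id)]
  if (any(is.na(key)) || any(!nzchar(key))) {
    stop("matrix contains unannotated probes; run dropUnannotated() first")
  }
  p <- unname(pvalues[rownames(se)])
  ord <- order(key, p, rownames(se))
  first <- !duplicated(key[ord])
  pick <- ord[first]
  out <- se[pick, ]
  rd <- SummarizedExperiment::rowData(out)
  rd$probe_id <- rownames(se)[pick]
  rd$collapse_p <- p[pick]
  SummarizedExperiment::rowData(out) <- rd
  rownames(out) <- key[pick]
  out[order(rownames(out)), ]
}
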