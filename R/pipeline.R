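#' Run the full inheritance-of-expression pipeline
#'
#' Orchestrates every stage: read (or simulate) the arrays, floor and
#' Lowess-normalize, apply the quality filter, restrict to annotated
#' probes, collapse to genes by lowest p-value (Welch t p for the
#' stock contrast; ANOVA p for the four-group analysis — the two collapsed
#' sets are kept separate), test differential expression between the pure
#' stocks, run the Welch ANOVA + SNK heritability analysis, and run the
#' gene-set perturbation tests. The run report logs probe/gene counts at
#' every filtering stage.
#'
#' @param input either a \code{\link{simConfig}} (the experiment is
#'   generated in memory) or a list of paths with elements
#'   \code{sampleSheet}, \code{annotation}, \code{gmt}.
#' @param alphaDe,fcThreshold stock-contrast significance and fold-change
#'   cutoffs.
#' @param anovaFdr BH cutoff gating the SNK post-hoc.
#' @param alphaSnk SNK per-step level.
#' @param qSet,p2dFocus gene-set significance and focused two-way cutoffs.
#' @param excludeGroups functional groups excluded from enrichment.
#' @param scheme parental-effect scheme (\code{"line"} or
#'   \code{"literal"}).
#' @param collapseOrder \code{"pre"} (default): collapse on raw p then
#'   BH-adjust the collapsed set; \code{"post"}: adjust before collapsing.
#' @param span Lowess span.
#' @param outdir optional directory for the output tables.
#' @return list with \code{report} (named stage counts), \code{se}
#'   (probe-level), \code{geneSE} (gene-level, stock-contrast collapse),
#'   \code{de}, \code{posthoc}, \code{calls}, \code{classTable},
#'   \code{enrichment} and, for simulated input, \code{truth}.
#' @export
runPipeline <- function(input, alphaDe = 0.05, fcThreshold = 1.25,
                        anovaFdr = 0.10, alphaSnk = 0.05, qSet = 0.1,
                        p2dFocus = 0.02, excludeGroups = "Human Diseases",
                        scheme = c("line", "literal"),
                        collapseOrder = c("pre", "post"),
                        span = 0.3, outdir = NULL) {
  scheme <- match.arg(scheme)
  collapseOrder <- match.arg(collapseOrder)
  truth <- NULL
  if (inherits(input, "SimConfig")) {
    sim <- simulateExperiment(input)
    batch <- sim$batch
    annotation <- sim$annotation
    geneSets <- sim$geneSets
    truth <- sim$truth
  } else {
    batch <- readFeatureTables(input$sampleSheet)
    annotation <- readAnnotation(input$annotation)
    geneSets <- readGMT(input$gmt)
  }
  report <- c(probes_read = nrow(batch))
  batch <- floorIntensities(batch)
  se <- lowessNormalize(batch, span = span)
  keep <- qcFilter(batch)
  se <- se[rownames(se) %in% keep, ]
  report["probes_qc"] <- nrow(se)
  se <- dropUnannotated(se, annotation)
  report["probes_annotated"] <- nrow(se)

  iW <- crossColumns(se, "WW"); iD <- crossColumns(se, "DD")
  M <- SummarizedExperiment::assay(se, "M")
  pT <- rowWelchT(M, iD, iW)$p
  if (collapseOrder == "post") pT <- bhAdjust(pT)
  names(pT) <- rownames(se)
  geneSE <- collapseToGenes(se, annotation, pT)
  report["genes_collapsed"] <- nrow(geneSE)

  pA <- rowWelchAnova(M, crossType(se))$p
  if (collapseOrder == "post") pA <- bhAdjust(pA)
  names(pA) <- rownames(se)
  geneSEAnova <- collapseToGenes(se, annotation, pA)

  de <- deBetweenStocks(geneSE, alpha = alphaDe, fcThreshold = fcThreshold)
  report["genes_de"] <- sum(de$significant)
  posthoc <- anovaPosthoc(geneSEAnova, fdrThreshold = anovaFdr,
                          alphaSnk = alphaSnk)
  report["genes_anova_significant"] <- sum(posthoc$anova_p_adj <= anovaFdr)
  calls <- heritabilityCalls(geneSEAnova, posthoc, scheme = scheme)
  report["genes_categorized"] <- length(unique(calls$gene_id))
  classTable <- heritabilityTable(calls)
  enrichment <- runEnrichment(geneSE, geneSets, qThreshold = qSet,
                              p2dFocus = p2dFocus,
                              excludeGroups = excludeGroups)
  out <- list(report = report, se = se, geneSE = geneSE,
              geneSEAnova = geneSEAnova, de = de, posthoc = posthoc,
              calls = calls, classTable = classTable,
              enrichment = enrichment, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) utils::write.table(
      x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    w(de, "de_stocks.tsv")
    w(posthoc, "anova_posthoc.tsv")
    w(calls, "heritability_calls.tsv")
    w(classTable, "heritability_table.tsv")
    w(enrichment, "enrichment.tsv")
    w(data.frame(stage = names(report), count = as.integer(report)),
      "run_report.tsv")
    writeExpressionMatrix(geneSE, file.path(outdir, "gene_matrix.tsv"))
  }
  out
}

#' Hierarchical clustering of differentially expressed genes
#'
#' Average-linkage agglomerative clustering with distance
#' 1 - Pearson correlation across arrays. Genes can be split into
#' up-/down-in-domesticated panels before clustering. Constant-expression
#' genes (undefined correlation) are placed at distance 1 from everything,
#' with a message. The dendrogram leaf order and merge heights are
#' returned for testability; a heatmap file is written only on request.
#'
#' @param se a \linkS4class{CrossExperiment} restricted to the genes of
#'   interest.
#' @param directionSplit split genes by the sign of the domesticated-minus-
#'   wild mean difference into separate panels.
#' @param file optional PNG path for a heatmap (drawn with pheatmap).
#' @return list of panels, each with \code{genes}, \code{leafOrder},
#'   \code{heights} and the \code{hclust} object.
#' @export
clusterHeatmap <- function(se, directionSplit = FALSE, file = NULL) {
  M <- SummarizedExperiment::assay(se, "M")
  if (nrow(M) < 2L) stop("need at least 2 genes to cluster")
  panels <- list(all = rownames(M))
  if (directionSplit) {
    d <- rowMeans(M[, crossColumns(se, "DD"), drop = FALSE]) -
      rowMeans(M[, crossColumns(se, "WW"), drop = FALSE])
    panels <- list(up = rownames(M)[d >= 0], down = rownames(M)[d < 0])
    panels <- panels[vapply(panels, length, 1L) >= 2L]
  }
  lapply(panels, function(genes) {
    X <- M[genes, , drop = FALSE]
    sds <- apply(X, 1L, stats::sd)
    if (any(sds == 0)) {
      message(sum(sds == 0), " constant-expression gene(s): ",
              "distance set to 1 against all others")
    }
    D <- 1 - suppressWarnings(stats::cor(t(X)))
    D[is.na(D)] <- 1
    diag(D) <- 0
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    if (!is.null(file) && requireNamespace("pheatmap", quietly = TRUE)) {
      grDevices::png(file, width = 900, height = 1200)
      pheatmap::pheatmap(X, cluster_rows = hc, cluster_cols = FALSE)
      grDevices::dev.off()
    }
    list(genes = genes, leafOrder = genes[hc$order],
         heights = hc$height, hclust = hc)
  })
}

#' Scatter plot of additivity against dominance ratio
#'
#' Plots alpha on the x axis against delta/alpha on the y axis, coloured
#' by hybrid. Points with |delta/alpha| above \code{cap} are omitted from
#' the figure only — summary tables always keep them.
#'
#' @param calls data.frame from \code{\link{heritabilityCalls}}.
#' @param cap plotting cap on |delta/alpha| (default 5; use \code{Inf} to
#'   plot everything).
#' @param file optional output file (any device ggplot2 supports).
#' @return list with \code{plot} (ggplot object), \code{nPlotted} and
#'   \code{nOmitted}.
#' @export
ratioScatter <- function(calls, cap = 5, file = NULL) {
  ok <- !is.na(calls$ratio) & abs(calls$ratio) <= cap
  if (!any(ok)) warning("no points to plot")
  df <- calls[ok, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = alpha, y = ratio,
                                        colour = hybrid)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = expression(alpha ~ "(additivity)"),
                  y = expression(delta / alpha),
                  colour = "Hybrid") +
    ggplot2::theme_bw()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 6, height = 5)
  list(plot = p, nPlotted = sum(ok),
       nOmitted = sum(!is.na(calls$ratio)) - sum(ok))
}
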