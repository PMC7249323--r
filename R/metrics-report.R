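#' Full hierarchy-aware metric report for one clustering
#'
#' End-to-end assembly: computes RI, ARI, wRI, wPPV, wNPV, MI, NMI, wMI and
#' wNMI for a clustering against a hierarchical reference. Weights and tree
#' can be supplied directly, or estimated from a labelled expression matrix
#' (mean type profiles, top variable genes, correlation weights,
#' complete-linkage tree); anything not supplied is estimated, and the
#' provenance block records which route produced each ingredient.
#'
#' @param ref reference \linkS4class{CellPartition}.
#' @param clust clustering \linkS4class{CellPartition} over the same cells.
#' @param weights optional \linkS4class{ClusterWeights}.
#' @param tree optional \linkS4class{ReferenceTree}.
#' @param expr optional genes x cells expression matrix used to estimate
#'   whichever of \code{weights} / \code{tree} is missing.
#' @param nGenes top-variable-gene count for estimation (default 1000).
#' @param base logarithm base for the information metrics (default e).
#' @return a \linkS4class{MetricReport}.
#' @examples
#' sim <- simulatePopulation(cellsPerType = 30, nGenes = 100, seed = 7)
#' cl <- perturbClustering(sim$labels, "merge_siblings", sim$tree, 10)
#' clusterMetrics(sim$labels, cl, expr = sim$expression, nGenes = 50)
#' @export
clusterMetrics <- function(ref, clust, weights = NULL, tree = NULL,
                           expr = NULL, nGenes = 1000L, base = exp(1)) {
  stopifnot(is(ref, "CellPartition"), is(clust, "CellPartition"))
  weightSource <- if (is.null(weights)) "estimated" else "supplied"
  treeSource <- if (is.null(tree)) "estimated" else "supplied"
  genesUsed <- NA_integer_
  if (is.null(weights) || is.null(tree)) {
    if (is.null(expr))
      .stopInput("weights/tree must be supplied directly or estimated from ",
                 "an expression matrix: pass 'weights' and 'tree', or 'expr'")
    prof <- meanProfiles(expr, ref)
    genes <- topVariableGenes(prof, nGenes)
    genesUsed <- length(genes)
    if (is.null(weights))
      weights <- ClusterWeights(w1 = estimateW1(prof, genes),
                                w0 = estimateW0(expr, ref, genes))
    if (is.null(tree))
      tree <- buildReferenceTree(prof, genes)
  }
  tree <- ReferenceTree(tree)
  ct <- buildContingency(ref, clust)
  pc <- pairCounts(ct)
  wpv <- suppressWarnings(weightedPredictiveValues(ct, weights = weights))
  wnmi <- weightedNMI(ref, tree, clust, base = base)
  metrics <- c(
    RI = randIndex(pc),
    ARI = adjustedRandIndex(ct),
    wRI = weightedRandIndex(ct, weights = weights),
    wpv,
    MI = mutualInformation(ct, base = base),
    NMI = nmi(ref, clust, base = base),
    wnmi)
  new("MetricReport", metrics = metrics, pairCounts = pc,
      provenance = list(
        n_cells = nCells(ref),
        n_types = length(groupLabels(ref)),
        n_clusters = length(groupLabels(clust)),
        weight_source = weightSource,
        tree_source = treeSource,
        n_genes_used = genesUsed,
        log_base = base,
        package_version = as.character(packageVersion("scHierEval"))))
}

# weightedRandIndex/weightedPredictiveValues accept a ContingencyTable as
# first argument; thin wrappers keep the call sites above readable
#' @rdname MetricReport-accessors
#' @export
setMethod("metricValues", "MetricReport", function(x) x@metrics)

#' Accessors for MetricReport
#'
#' @param x a \linkS4class{MetricReport}.
#' @return \code{metricValues}: named numeric vector of all scores;
#'   \code{provenance}: list recording how weights/tree were obtained.
#' @name MetricReport-accessors
#' @aliases metricValues provenance metricValues,MetricReport-method
#'   provenance,MetricReport-method
NULL

#' @rdname MetricReport-accessors
#' @export
setMethod("provenance", "MetricReport", function(x) x@provenance)

setMethod("show", "MetricReport", function(object) {
  p <- object@provenance
  cat("MetricReport:", p$n_cells, "cells,", p$n_types, "types vs",
      p$n_clusters, "clusters (weights ", p$weight_source, ", tree ",
      p$tree_source, ")\n", sep = " ")
  m <- object@metrics
  out <- format(round(m, 3), nsmall = 3)
  cat(paste0(format(names(m), width = 5), " ", out, collapse = "\n"), "\n")
})

#' Tabulate metric reports for several clusterings
#'
#' @param reports named list of \linkS4class{MetricReport}s (e.g. one per
#'   clustering method).
#' @return data.frame with one row per report and one column per metric.
#' @export
metricsTable <- function(reports) {
  stopifnot(length(reports) > 0,
            all(vapply(reports, is, logical(1), "MetricReport")))
  df <- do.call(rbind, lapply(reports, function(r) as.data.frame(t(r@metrics))))
  rownames(df) <- names(reports)
  df
}
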