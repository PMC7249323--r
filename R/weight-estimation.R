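#' Mean log-expression profile per reference cell type
#'
#' Averages \code{log(x + 1)}-transformed expression over the cells of each
#' reference type. The pseudocount makes the transform defined on the
#' zero-heavy counts typical of scRNA-seq; the log base only rescales every
#' downstream variance and correlation by a constant and is therefore
#' immaterial for gene selection and weight estimation.
#'
#' @param expr genes x cells matrix (dense or \code{Matrix} sparse) of
#'   non-negative expression values with gene and cell dimnames.
#' @param ref reference \linkS4class{CellPartition} labelling every cell of
#'   \code{expr}.
#' @param log apply the log1p transform (default TRUE); set FALSE if the
#'   matrix is already on a log scale.
#' @return types x genes numeric matrix of mean profiles, with an attribute
#'   \code{cellCounts} giving the number of cells per type.
#' @export
meanProfiles <- function(expr, ref, log = TRUE) {
  stopifnot(is(ref, "CellPartition"))
  expr <- .checkExpr(expr)
  miss <- setdiff(ref@cellIds, colnames(expr))
  if (length(miss))
    .stopInput("cells absent from the expression matrix: ",
               paste(head(miss, 5L), collapse = ", "))
  types <- groupLabels(ref)
  lab <- cellLabels(ref)
  prof <- matrix(0, length(types), nrow(expr),
                 dimnames = list(types, rownames(expr)))
  counts <- integer(length(types))
  for (j in seq_along(types)) {
    cells <- names(lab)[lab == types[j]]
    counts[j] <- length(cells)
    x <- as.matrix(expr[, cells, drop = FALSE])
    if (log) x <- log1p(x)
    prof[j, ] <- rowMeans(x)
  }
  if (any(counts == 0L))
    .stopInput("reference types with zero cells: ",
               paste(types[counts == 0L], collapse = ", "))
  attr(prof, "cellCounts") <- setNames(counts, types)
  prof
}

.checkExpr <- function(expr) {
  if (!(is.matrix(expr) || is(expr, "Matrix")))
    .stopInput("expression must be a genes x cells matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    .stopInput("expression matrix needs gene and cell dimnames")
  if (anyDuplicated(rownames(expr)) || anyDuplicated(colnames(expr)))
    .stopInput("gene and cell ids must be unique")
  if (min(expr) < 0) .stopInput("expression values must be non-negative")
  expr
}

#' Select the most variable genes across type mean profiles
#'
#' Ranks genes by the variance of their mean log expression across cell
#' types and returns the indices of the top k, the marker set used for
#' weight and tree estimation. Ties are broken by gene order (stable).
#'
#' @param profiles types x genes matrix from \code{\link{meanProfiles}}.
#' @param k number of genes to keep (default 1000); capped at the gene
#'   count with a warning.
#' @return integer vector of gene column indices, variance-descending.
#' @export
topVariableGenes <- function(profiles, k = 1000L) {
  if (ncol(profiles) < 2L) .stopInput("need at least 2 genes")
  if (k < 1L) .stopInput("k must be positive")
  if (k > ncol(profiles)) {
    warning("k = ", k, " exceeds the ", ncol(profiles),
            " available genes; using all")
    k <- ncol(profiles)
  }
  v <- apply(profiles, 2L, var)
  head(order(-v, seq_along(v)), k)
}

#' Estimate the same-cluster weight matrix W1 from mean profiles
#'
#' \code{w1[i, j]} is the Pearson correlation of the mean log-expression
#' profiles of types i and j over the selected genes, so closely related
#' types retain most of the credit for being co-clustered. The diagonal is
#' fixed at 1 and negative correlations are clamped to 0 to keep the
#' canonical range.
#'
#' @param profiles types x genes matrix from \code{\link{meanProfiles}}.
#' @param genes gene indices from \code{\link{topVariableGenes}} (default:
#'   all genes).
#' @return a J x J \code{w1} matrix (plain matrix; combine with a
#'   \code{w0} via \code{\link{ClusterWeights}} or use
#'   \code{\link{estimateWeights}}).
#' @export
estimateW1 <- function(profiles, genes = seq_len(ncol(profiles))) {
  if (nrow(profiles) < 2L) .stopInput("need at least 2 types")
  sub <- t(profiles[, genes, drop = FALSE])
  sds <- apply(sub, 2L, sd)
  if (any(sds == 0))
    .stopInput("zero-variance profile over the selected genes for type(s): ",
               paste(rownames(profiles)[sds == 0], collapse = ", "))
  w1 <- cor(sub)
  w1[w1 < 0] <- 0
  diag(w1) <- 1
  w1
}

#' Estimate the different-cluster weight matrix W0 from single cells
#'
#' The off-diagonal is 1 (separating different types always gets full
#' credit). The diagonal entry for type i measures the type's internal
#' heterogeneity: with \code{method = "pairwise"} (default) it is one minus
#' the average pairwise Pearson correlation among that type's cells over
#' the selected genes; with \code{method = "to-mean"} it is the average
#' dissimilarity \code{1 - r} between each cell and the type's mean
#' profile. Either way a homogeneous type gets a diagonal near 0 (full
#' penalty for splitting it) and a heterogeneous type a value near 1
#' (splitting tolerated). Values are clamped into [0, 1]. A type with a
#' single cell has no measurable heterogeneity and gets 0 with a warning.
#'
#' @inheritParams meanProfiles
#' @param genes gene row indices to use (default: all genes).
#' @param method heterogeneity estimator, see above.
#' @return a J x J \code{w0} matrix.
#' @export
estimateW0 <- function(expr, ref, genes = seq_len(nrow(expr)),
                       method = c("pairwise", "to-mean"), log = TRUE) {
  method <- match.arg(method)
  stopifnot(is(ref, "CellPartition"))
  expr <- .checkExpr(expr)
  types <- groupLabels(ref)
  lab <- cellLabels(ref)
  J <- length(types)
  w0 <- matrix(1, J, J, dimnames = list(types, types))
  for (j in seq_len(J)) {
    cells <- names(lab)[lab == types[j]]
    if (length(cells) < 2L) {
      warning("type '", types[j],
              "' has a single cell; heterogeneity set to 0")
      w0[j, j] <- 0
      next
    }
    x <- as.matrix(expr[genes, cells, drop = FALSE])
    if (log) x <- log1p(x)
    sds <- apply(x, 2L, sd)
    if (any(sds == 0))
      .stopInput("cells of type '", types[j],
                 "' have zero-variance profiles over the selected genes; ",
                 "correlation undefined")
    r <- if (method == "pairwise") {
      cm <- cor(x)
      mean(cm[upper.tri(cm)])
    } else {
      mean(cor(x, rowMeans(x)))
    }
    w0[j, j] <- min(max(1 - r, 0), 1)
  }
  w0
}

#' Estimate both weight matrices from a labelled expression matrix
#'
#' Convenience wrapper: computes mean profiles, selects the top variable
#' genes, and assembles \code{\link{estimateW1}} and \code{\link{estimateW0}}
#' into a \linkS4class{ClusterWeights}. The same gene set is used for both
#' matrices and for \code{\link{buildReferenceTree}}.
#'
#' @inheritParams meanProfiles
#' @param nGenes number of top variable genes (default 1000).
#' @param w0Method heterogeneity estimator, see \code{\link{estimateW0}}.
#' @return a \linkS4class{ClusterWeights}.
#' @export
estimateWeights <- function(expr, ref, nGenes = 1000L,
                            w0Method = c("pairwise", "to-mean")) {
  prof <- meanProfiles(expr, ref)
  genes <- topVariableGenes(prof, nGenes)
  ClusterWeights(w1 = estimateW1(prof, genes),
                 w0 = estimateW0(expr, ref, genes,
                                 method = match.arg(w0Method)))
}

#' Build the reference cell-type tree from mean profiles
#'
#' Agglomerative hierarchical clustering of the type mean log-expression
#' profiles over the selected genes (complete linkage on Euclidean distance
#' by default, matching standard practice), with all node heights divided
#' by the maximum so the root sits at height 1 and the first step weight is
#' d1 = 1.
#'
#' @param profiles types x genes matrix from \code{\link{meanProfiles}}.
#' @param genes gene indices (default: all genes).
#' @param linkage agglomeration method passed to \code{hclust}.
#' @return a \linkS4class{ReferenceTree} with root height 1.
#' @export
buildReferenceTree <- function(profiles, genes = seq_len(ncol(profiles)),
                               linkage = "complete") {
  if (nrow(profiles) < 2L) .stopInput("need at least 2 types")
  d <- dist(profiles[, genes, drop = FALSE])
  if (max(d) == 0)
    .stopDegenerate("all type profiles identical; tree is degenerate")
  referenceTreeFromHclust(hclust(d, method = linkage))
}

#' Convert an hclust merge structure to a ReferenceTree
#'
#' Accepts the output of \code{stats::hclust} (or anything following its
#' merge/height contract, e.g. a merge table read back from a file) and
#' standardizes the node heights by the maximum, so the root is at height 1.
#'
#' @param hc an \code{hclust} object whose labels are the cell types.
#' @return a \linkS4class{ReferenceTree}.
#' @export
referenceTreeFromHclust <- function(hc) {
  if (!inherits(hc, "hclust")) .stopInput("expected an 'hclust' object")
  if (max(hc$height) <= 0) .stopDegenerate("all merge heights are zero")
  phy <- ape::as.phylo(hc)
  # as.phylo halves hclust heights; rescale so the root height is exactly 1
  depth <- ape::node.depth.edgelength(phy)
  phy$edge.length <- phy$edge.length / max(depth)
  ReferenceTree(phy)
}
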