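#' @import methods
#' @importFrom stats cor dist hclust rnorm rnbinom var sd setNames
#' @importFrom utils head read.csv write.csv packageVersion
NULL

setOldClass("phylo")

# internal condition helpers: input-schema errors vs degenerate-metric errors,
# used by the CLI to map failures onto exit codes
.stopInput <- function(...) {
  stop(structure(
    class = c("scHierEval_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

.stopDegenerate <- function(...) {
  stop(structure(
    class = c("scHierEval_degenerate_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' CellPartition: a labelled partition of a cell population
#'
#' Represents one partition of a set of cells: either the reference cell-type
#' assignment (J types) or a clustering result (I clusters). Every cell
#' carries exactly one opaque string label; cells are identified by unique
#' ids so that two partitions can be matched by id rather than by row order.
#'
#' @slot cellIds character vector of unique cell identifiers.
#' @slot labels character vector of group labels, parallel to \code{cellIds}.
#'
#' @examples
#' ref <- CellPartition(c("A", "A", "B", "B"))
#' groupLabels(ref)
#' @aliases CellPartition-class
#' @exportClass CellPartition
setClass("CellPartition",
  representation(cellIds = "character", labels = "character")
)

setValidity("CellPartition", function(object) {
  msg <- character()
  n <- length(object@cellIds)
  if (n < 2L) msg <- c(msg, "a partition needs at least 2 cells")
  if (length(object@labels) != n)
    msg <- c(msg, "labels and cellIds must have the same length")
  if (anyNA(object@cellIds) || anyNA(object@labels))
    msg <- c(msg, "cell ids and labels must not contain NA")
  if (anyDuplicated(object@cellIds)) {
    dup <- unique(object@cellIds[duplicated(object@cellIds)])
    msg <- c(msg, paste0("duplicated cell ids: ",
                         paste(head(dup, 5L), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' @param labels character vector of group labels (or anything coercible).
#' @param cellIds optional character vector of unique ids; defaults to the
#'   names of \code{labels}, or \code{cell1..celln}.
#' @rdname CellPartition-class
#' @export
CellPartition <- function(labels, cellIds = NULL) {
  if (is.null(cellIds)) {
    cellIds <- if (!is.null(names(labels))) names(labels)
               else paste0("cell", seq_along(labels))
  }
  new("CellPartition", cellIds = as.character(cellIds),
      labels = as.character(labels))
}

#' ContingencyTable: J x I cross-tabulation of two partitions
#'
#' Counts of cells by (reference type, cluster). Rows are reference types in
#' first-appearance order of the reference; columns are clusters in
#' first-appearance order of the clustering, so the matrix is interpretable
#' against the weight matrices.
#'
#' @slot counts numeric J x I matrix of non-negative integer counts, with
#'   reference types as rownames and cluster labels as colnames.
#' @aliases ContingencyTable-class
#' @exportClass ContingencyTable
setClass("ContingencyTable", representation(counts = "matrix"))

setValidity("ContingencyTable", function(object) {
  ct <- object@counts
  msg <- character()
  if (!is.numeric(ct)) msg <- c(msg, "counts must be numeric")
  else {
    if (any(ct < 0) || any(ct != round(ct)))
      msg <- c(msg, "counts must be non-negative integers")
    if (sum(ct) < 2) msg <- c(msg, "table must hold at least 2 cells")
  }
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    msg <- c(msg, "counts must carry row (type) and column (cluster) names")
  if (length(msg)) msg else TRUE
})

#' @param counts a named numeric matrix of cell counts.
#' @rdname ContingencyTable-class
#' @export
ContingencyTable <- function(counts) {
  new("ContingencyTable", counts = counts)
}

#' ClusterWeights: the W1 / W0 score matrices for weighted Rand index
#'
#' J x J matrices scoring each pair of reference types: \code{w1[i, j]} is
#' the reward for co-clustering a cell of type i with one of type j;
#' \code{w0[i, j]} is the reward for separating them. In the canonical form
#' \code{diag(w1) = 1} (recovering a reference tie gets full credit, forming
#' a new tie partial credit) and the off-diagonal of \code{w0} is 1 (keeping
#' reference separations gets full credit), while \code{diag(w0)} in [0, 1]
#' expresses tolerance for splitting a heterogeneous type.
#'
#' Matrices are symmetrized from the upper triangle; a lower triangle that
#' disagrees with the upper one beyond 1e-8 is an error, and \code{NA}s in
#' the lower triangle are filled in from the upper.
#'
#' @slot w1 J x J numeric matrix of same-cluster scores.
#' @slot w0 J x J numeric matrix of different-cluster scores.
#' @slot typeLabels ordered reference type labels.
#' @aliases ClusterWeights-class
#' @exportClass ClusterWeights
setClass("ClusterWeights",
  representation(w1 = "matrix", w0 = "matrix", typeLabels = "character")
)

setValidity("ClusterWeights", function(object) {
  msg <- character()
  J <- length(object@typeLabels)
  for (nm in c("w1", "w0")) {
    w <- slot(object, nm)
    if (!all(dim(w) == c(J, J)))
      msg <- c(msg, paste0(nm, " must be ", J, "x", J))
    else {
      if (anyNA(w)) msg <- c(msg, paste0(nm, " contains missing entries"))
      else {
        if (any(w < 0 | w > 1))
          msg <- c(msg, paste0(nm, " entries must lie in [0, 1]"))
        if (max(abs(w - t(w))) > 1e-8)
          msg <- c(msg, paste0(nm, " must be symmetric"))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

.symmetrizeUpper <- function(w, name) {
  if (!is.matrix(w) || nrow(w) != ncol(w))
    .stopInput(name, " must be a square matrix")
  lo <- lower.tri(w)
  up <- t(w)[lo]                      # upper-triangle values, mirrored
  present <- !is.na(w[lo])
  if (any(present) && any(abs(w[lo][present] - up[present]) > 1e-8))
    .stopInput(name, " upper and lower triangles disagree beyond 1e-8")
  w[lo] <- up
  w
}

#' @param w1,w0 J x J numeric matrices (upper triangle authoritative).
#' @param typeLabels reference type labels; defaults to rownames of w1.
#' @param canonical enforce the canonical form (diag(w1) = 1, off-diagonal
#'   of w0 = 1)? Defaults to TRUE; disable for exploratory weighting schemes.
#' @rdname ClusterWeights-class
#' @export
ClusterWeights <- function(w1, w0, typeLabels = rownames(w1),
                           canonical = TRUE) {
  if (is.null(typeLabels))
    .stopInput("weight matrices need type labels (rownames) or typeLabels=")
  typeLabels <- as.character(typeLabels)
  w1 <- .symmetrizeUpper(as.matrix(w1), "w1")
  w0 <- .symmetrizeUpper(as.matrix(w0), "w0")
  dimnames(w1) <- dimnames(w0) <- list(typeLabels, typeLabels)
  if (canonical) {
    if (any(abs(diag(w1) - 1) > 1e-8))
      .stopInput("canonical w1 must have unit diagonal ",
                 "(use canonical = FALSE to override)")
    off <- w0[upper.tri(w0)]
    if (length(off) && any(abs(off - 1) > 1e-8))
      .stopInput("canonical w0 must have unit off-diagonal ",
                 "(use canonical = FALSE to override)")
  }
  new("ClusterWeights", w1 = w1, w0 = w0, typeLabels = typeLabels)
}

#' ReferenceTree: ultrametric cell-type hierarchy with node heights
#'
#' A rooted dendrogram whose leaves are the reference cell types. Node
#' heights (distance above the leaf level, root highest) define a sequence
#' of nested partitions R1..RJ obtained by cutting below successively lower
#' internal nodes, and standardized step weights d1..d(J-1) (height of the
#' j-th cut divided by the maximum height, so d1 = 1). Multifurcating nodes
#' are expanded into consecutive equal-height binary steps so the partition
#' sequence refines by exactly one group per step.
#'
#' @slot tree an ultrametric \code{ape::phylo} with branch lengths.
#' @slot heights numeric vector of internal-node heights, named by the
#'   phylo node number.
#' @slot maxHeight height of the root.
#' @aliases ReferenceTree-class
#' @exportClass ReferenceTree
setClass("ReferenceTree",
  representation(tree = "phylo", heights = "numeric", maxHeight = "numeric")
)

setValidity("ReferenceTree", function(object) {
  msg <- character()
  if (length(object@tree$tip.label) < 2L)
    msg <- c(msg, "tree needs at least 2 leaves")
  if (anyDuplicated(object@tree$tip.label))
    msg <- c(msg, "leaf labels must be unique")
  if (any(object@heights <= 0))
    msg <- c(msg, "internal node heights must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' @param tree an \code{ape::phylo} object with branch lengths, ultrametric
#'   up to \code{tol} (every leaf equidistant from the root).
#' @param tol relative tolerance for the ultrametric check (default 1e-6).
#' @rdname ReferenceTree-class
#' @export
ReferenceTree <- function(tree, tol = 1e-6) {
  if (inherits(tree, "ReferenceTree")) return(tree)
  if (!inherits(tree, "phylo"))
    .stopInput("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length))
    .stopInput("tree must carry branch lengths")
  if (any(tree$edge.length < 0))
    .stopInput("branch lengths must be non-negative")
  nTip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)   # root-to-node path lengths
  leafDepth <- depth[seq_len(nTip)]
  maxDepth <- max(leafDepth)
  if (maxDepth <= 0)
    .stopInput("degenerate tree: all branch lengths are zero")
  if (max(maxDepth - leafDepth) > tol * maxDepth)
    .stopInput("tree is not ultrametric within tolerance ", tol,
               " (leaf depths range ", format(min(leafDepth)), " to ",
               format(maxDepth), ")")
  internal <- nTip + seq_len(tree$Nnode)
  heights <- maxDepth - depth[internal]
  names(heights) <- as.character(internal)
  new("ReferenceTree", tree = tree, heights = heights, maxHeight = maxDepth)
}

#' MetricReport: all agreement scores for one clustering-vs-reference run
#'
#' Bundles the classical (RI, ARI, MI, NMI) and hierarchy-aware (wRI, wPPV,
#' wNPV, wMI, wNMI) scores for one comparison together with the pair counts
#' and a provenance block recording where weights and tree came from, so
#' every number is reproducible from the record.
#'
#' @slot metrics named numeric vector of scores.
#' @slot pairCounts named numeric vector (N11, N10, N01, N00, N).
#' @slot provenance list describing inputs (weight source, tree source,
#'   gene count used for estimation, package version).
#' @aliases MetricReport-class
#' @exportClass MetricReport
setClass("MetricReport",
  representation(metrics = "numeric", pairCounts = "numeric",
                 provenance = "list")
)
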