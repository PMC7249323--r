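#' Accessors for ReferenceTree
#'
#' @param x a \linkS4class{ReferenceTree}.
#' @return \code{typeLabels}: leaf (cell-type) labels; \code{treeHeights}:
#'   internal node heights above the leaf level, named by phylo node number,
#'   with the root equal to \code{max}; \code{nCells} is not defined (trees
#'   describe types, not cells).
#' @name ReferenceTree-accessors
#' @aliases typeLabels,ReferenceTree-method treeHeights
#'   treeHeights,ReferenceTree-method
NULL

#' @rdname ReferenceTree-accessors
#' @export
setMethod("typeLabels", "ReferenceTree", function(x) x@tree$tip.label)

#' @rdname ReferenceTree-accessors
#' @export
setMethod("treeHeights", "ReferenceTree", function(x) x@heights)

setMethod("show", "ReferenceTree", function(object) {
  J <- length(object@tree$tip.label)
  cat("ReferenceTree over", J, "cell types, root height",
      format(object@maxHeight, digits = 4), "\n")
  cat("  step weights d:",
      paste(format(stepWeights(object), digits = 3), collapse = ", "), "\n")
})

# Ordered binary split steps of the dendrogram. Internal nodes are processed
# from the root down (height descending; ties broken parent-first by depth,
# then by node number); a node with m children contributes m - 1 consecutive
# steps at its height, splitting off one child at a time, so each step takes
# the leaf partition from j to j + 1 groups.
#
# Returns list(heights = numeric[J - 1],
#              membership = J x J integer matrix: row j = group index of
#              each leaf in partition R_j, leaves in tip order).
.treeSteps <- function(rt) {
  phy <- rt@tree
  nTip <- length(phy$tip.label)
  nodes <- nTip + seq_len(phy$Nnode)
  depth <- ape::node.depth.edgelength(phy)
  children <- split(phy$edge[, 2], factor(phy$edge[, 1], levels = nodes))
  ord <- nodes[order(-rt@heights, depth[nodes], nodes)]
  # leaves under each node
  leafSets <- vector("list", nTip + phy$Nnode)
  for (i in seq_len(nTip)) leafSets[[i]] <- i
  for (v in rev(ord))
    leafSets[[v]] <- sort(unlist(leafSets[children[[as.character(v)]]]))
  assign <- rep(1L, nTip)
  membership <- matrix(0L, nrow = 0, ncol = nTip)
  membership <- rbind(membership, assign)
  heights <- numeric(0)
  nextGroup <- 1L
  for (v in ord) {
    kids <- children[[as.character(v)]]
    for (k in seq_len(length(kids) - 1L)) {
      nextGroup <- nextGroup + 1L
      assign[leafSets[[kids[k]]]] <- nextGroup
      membership <- rbind(membership, assign)
      heights <- c(heights, rt@heights[as.character(v)])
    }
  }
  rownames(membership) <- NULL
  list(heights = unname(heights), membership = membership)
}

#' Standardized step weights of the reference hierarchy
#'
#' The dendrogram heights at which the nested partitions R1..RJ split, in
#' cut order (root first), divided by the maximum height: d_j is the cost of
#' distinguishing j groups from j + 1, with d1 = 1 and d non-increasing.
#' Multifurcations repeat their height once per extra child.
#'
#' @param tree a \linkS4class{ReferenceTree}.
#' @return numeric vector d of length J - 1.
#' @export
stepWeights <- function(tree) {
  tree <- ReferenceTree(tree)
  .treeSteps(tree)$heights / tree@maxHeight
}

#' Nested partitions from cutting the reference tree
#'
#' Cuts the dendrogram below successively lower internal nodes, producing
#' partitions R1 (everything in one group) through RJ (the leaf-level
#' typing), each refining the previous by splitting exactly one group. The
#' partitions are returned over cells, mapping each cell through its
#' reference type; group labels are the member type names joined by "+".
#'
#' @param tree a \linkS4class{ReferenceTree} whose leaves include every
#'   reference type.
#' @param ref the reference \linkS4class{CellPartition}.
#' @return list of J \linkS4class{CellPartition}s.
#' @export
cutPartitions <- function(tree, ref) {
  tree <- ReferenceTree(tree)
  stopifnot(is(ref, "CellPartition"))
  tips <- tree@tree$tip.label
  miss <- setdiff(groupLabels(ref), tips)
  if (length(miss))
    .stopInput("reference types missing from the tree: ",
               paste(miss, collapse = ", "))
  steps <- .treeSteps(tree)
  typeIdx <- match(ref@labels, tips)
  lapply(seq_len(nrow(steps$membership)), function(j) {
    grp <- steps$membership[j, ]
    lab <- vapply(seq_len(ncol(steps$membership)), function(i)
      paste(sort(tips[grp == grp[i]]), collapse = "+"), character(1))
    CellPartition(lab[typeIdx], cellIds = ref@cellIds)
  })
}

# Shannon entropy of a label vector (natural log); 0 log 0 := 0
.entropyOf <- function(labels, base = exp(1)) {
  p <- tabulate(match(labels, unique(labels))) / length(labels)
  -sum(p * log(p, base = base))
}

#' Shannon entropy of a partition
#'
#' \eqn{H = -\sum_j p_j \log p_j} over the group proportions, in natural-log
#' units (nats) by default. The base cancels in every normalized metric.
#'
#' @param p a \linkS4class{CellPartition}.
#' @param base logarithm base (default e).
#' @return entropy in units of \code{log(base)}.
#' @export
partitionEntropy <- function(p, base = exp(1)) {
  stopifnot(is(p, "CellPartition"))
  .entropyOf(p@labels, base = base)
}

#' Mutual information between two partitions
#'
#' \eqn{MI = \sum_{ji} (n_{ji}/n) \log(n\, n_{ji} / (n_{j+} n_{+i}))}, the
#' entropy of the reference explained by the clustering. Zero cells are
#' skipped.
#'
#' @param ct a \linkS4class{ContingencyTable}.
#' @param base logarithm base (default e).
#' @return MI in units of \code{log(base)}.
#' @export
mutualInformation <- function(ct, base = exp(1)) {
  stopifnot(is(ct, "ContingencyTable"))
  n <- nCells(ct)
  rm <- rowMargins(ct); cm <- colMargins(ct)
  nz <- which(ct@counts > 0, arr.ind = TRUE)
  v <- ct@counts[nz]
  sum(v / n * log(n * v / (rm[nz[, 1]] * cm[nz[, 2]]), base = base))
}

#' Normalized mutual information
#'
#' MI divided by the arithmetic mean of the two partition entropies,
#' \eqn{NMI = MI / ((H(R) + H(C)) / 2)}, in [0, 1].
#'
#' @param ref,clust \linkS4class{CellPartition}s over the same cell ids.
#' @param base logarithm base (default e); the value is base-invariant.
#' @return the NMI score.
#' @export
nmi <- function(ref, clust, base = exp(1)) {
  ct <- buildContingency(ref, clust)
  hr <- partitionEntropy(ref, base); hc <- partitionEntropy(clust, base)
  if (hr + hc <= 0)
    .stopDegenerate("NMI undefined: both partitions are trivial")
  mutualInformation(ct, base) / ((hr + hc) / 2)
}

# joint entropy of two parallel label vectors
.jointEntropy <- function(a, b, base = exp(1)) {
  .entropyOf(paste(a, b, sep = "\r"), base = base)
}

# conditional entropy H(A | B) via the joint-entropy identity
.condEntropy <- function(a, b, base = exp(1)) {
  .jointEntropy(a, b, base) - .entropyOf(b, base)
}

# oracle route: H(A | B) as the cluster-size-weighted average of within-
# cluster entropies; used to cross-check the joint-entropy identity
.condEntropyByCluster <- function(a, b, base = exp(1)) {
  n <- length(a)
  sum(vapply(unique(b), function(g) {
    idx <- b == g
    sum(idx) / n * .entropyOf(a[idx], base = base)
  }, numeric(1)))
}

#' Structured entropy of a hierarchical reference
#'
#' The dendrogram-weighted entropy
#' \eqn{H^*(R) = \sum_{j=1}^{J-1} d_j\, H(R_{j+1} | R_j)}, where R_j are the
#' nested tree-cut partitions and d_j the standardized step heights. Because
#' the partitions are nested, \eqn{H(R_{j+1} | R_j) = H(R_{j+1}) - H(R_j)}.
#' With all d_j = 1 this is the ordinary entropy H(R); small d values
#' discount the information needed to distinguish closely related types.
#'
#' @param ref reference \linkS4class{CellPartition}.
#' @param tree a \linkS4class{ReferenceTree} over the reference types.
#' @param base logarithm base (default e).
#' @return the scalar H*(R).
#' @export
structuredEntropy <- function(ref, tree, base = exp(1)) {
  cuts <- cutPartitions(tree, ref)
  d <- stepWeights(tree)
  H <- vapply(cuts, partitionEntropy, numeric(1), base = base)
  sum(d * diff(H))
}

#' Structured conditional entropy given a clustering
#'
#' \eqn{H^*(R | C) = \sum_j d_j\, H(R_{j+1} | R_j, C)}: the part of the
#' structured entropy the clustering fails to explain. Nestedness gives
#' \eqn{H(R_{j+1} | R_j, C) = H(R_{j+1} | C) - H(R_j | C)}, each term
#' computed through the joint-entropy identity
#' \eqn{H(R_j | C) = H(R_j, C) - H(C)}.
#'
#' @inheritParams structuredEntropy
#' @param clust clustering \linkS4class{CellPartition} over the same cells.
#' @return the scalar H*(R | C).
#' @export
structuredConditionalEntropy <- function(ref, tree, clust, base = exp(1)) {
  stopifnot(is(clust, "CellPartition"))
  cuts <- cutPartitions(tree, ref)
  d <- stepWeights(tree)
  cl <- cellLabels(clust)[ref@cellIds]
  if (anyNA(cl)) .stopInput("cell id sets differ between partitions")
  Hc <- vapply(cuts, function(p) .condEntropy(p@labels, cl, base), numeric(1))
  sum(d * diff(Hc))
}

#' Weighted mutual information and weighted NMI
#'
#' The hierarchy-aware analogues of MI and NMI:
#' \eqn{wMI = H^*(R) - H^*(R | C)} and
#' \deqn{wNMI = \frac{wMI}{H^*(R)} \cdot \frac{H(R)}{(H(R) + H(C)) / 2}.}
#' The first factor is the fraction of structured entropy explained by the
#' clustering; the second balances the relative complexity of the two
#' partitions, penalizing gross over-splitting. With all step weights equal
#' to 1 the pair reduces exactly to (MI, NMI). wNMI can exceed 1 when a
#' coarse clustering merges types separated only by a very small dendrogram
#' height; the value is reported as computed, not clipped.
#'
#' @inheritParams structuredConditionalEntropy
#' @return named numeric \code{c(wMI, wNMI)}.
#' @examples
#' ref <- CellPartition(rep(c("A1", "A2", "B"), c(2, 2, 4)))
#' tr <- ReferenceTree(ape::read.tree(text = "((A1:0.2,A2:0.2):0.8,B:1);"))
#' weightedNMI(ref, tr, CellPartition(rep(c("a", "b"), c(4, 4))))
#' @export
weightedNMI <- function(ref, tree, clust, base = exp(1)) {
  if (length(groupLabels(ref)) < 2L)
    .stopDegenerate("weighted NMI undefined for a single-type reference")
  hStar <- structuredEntropy(ref, tree, base)
  if (hStar <= 0)
    .stopDegenerate("structured entropy is zero; wNMI undefined")
  hr <- partitionEntropy(ref, base); hc <- partitionEntropy(clust, base)
  if (hr + hc <= 0)
    .stopDegenerate("wNMI undefined: both partitions are trivial")
  wMI <- hStar - structuredConditionalEntropy(ref, tree, clust, base)
  c(wMI = wMI, wNMI = wMI / hStar * hr / ((hr + hc) / 2))
}
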