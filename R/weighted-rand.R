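#' Identity weights: the classical Rand index as a special case
#'
#' Builds the weight pair that reduces the weighted agreement score to the
#' unweighted one: \code{w1} is the identity matrix and \code{w0 = 1 - w1},
#' so co-clustering same-type cells and separating different-type cells each
#' score 1 and everything else scores 0.
#'
#' @param types character vector of reference type labels.
#' @return a \linkS4class{ClusterWeights}.
#' @export
identityWeights <- function(types) {
  types <- as.character(types)
  J <- length(types)
  w1 <- diag(1, J)
  dimnames(w1) <- list(types, types)
  ClusterWeights(w1 = w1, w0 = 1 - w1)
}

#' Derive weight matrices from a reference tree
#'
#' A convenience weighting scheme read off the cell-type hierarchy:
#' \code{w1[i, j] = 1 - h(i, j) / hmax}, where \code{h(i, j)} is the height
#' of the most recent common ancestor of types i and j, so types merging low
#' in the dendrogram keep most of the co-clustering credit. \code{w0} has
#' unit off-diagonal and a constant diagonal \code{w0Diag} (default 0: full
#' penalty for splitting any type).
#'
#' @param tree a \linkS4class{ReferenceTree} (or phylo coercible to one).
#' @param w0Diag within-type splitting tolerance in [0, 1], recycled across
#'   types.
#' @return a \linkS4class{ClusterWeights} over the tree's leaf types.
#' @export
treeWeights <- function(tree, w0Diag = 0) {
  tree <- ReferenceTree(tree)
  types <- tree@tree$tip.label
  coph <- ape::cophenetic.phylo(tree@tree)[types, types]
  w1 <- 1 - coph / (2 * tree@maxHeight)   # ultrametric: mrca height = d/2
  w1 <- pmin(pmax(w1, 0), 1)
  diag(w1) <- 1
  J <- length(types)
  w0 <- matrix(1, J, J, dimnames = list(types, types))
  diag(w0) <- rep_len(w0Diag, J)
  ClusterWeights(w1 = w1, w0 = w0)
}

#' Accessors for ClusterWeights
#'
#' @param x a \linkS4class{ClusterWeights}.
#' @return \code{sameClusterWeights}: the W1 matrix; \code{diffClusterWeights}:
#'   the W0 matrix; \code{typeLabels}: reference type labels.
#' @name ClusterWeights-accessors
#' @aliases sameClusterWeights diffClusterWeights typeLabels
#'   sameClusterWeights,ClusterWeights-method
#'   diffClusterWeights,ClusterWeights-method
#'   typeLabels,ClusterWeights-method
NULL

#' @rdname ClusterWeights-accessors
#' @export
setMethod("sameClusterWeights", "ClusterWeights", function(x) x@w1)

#' @rdname ClusterWeights-accessors
#' @export
setMethod("diffClusterWeights", "ClusterWeights", function(x) x@w0)

#' @rdname ClusterWeights-accessors
#' @export
setMethod("typeLabels", "ClusterWeights", function(x) x@typeLabels)

setMethod("show", "ClusterWeights", function(object) {
  cat("ClusterWeights over", length(object@typeLabels), "types:",
      paste(head(object@typeLabels, 8L), collapse = ", "),
      if (length(object@typeLabels) > 8L) "..." else "", "\n")
})

# reorder weight matrices to the contingency table's type order
.alignWeights <- function(ct, weights) {
  types <- rownames(ct@counts)
  miss <- setdiff(types, weights@typeLabels)
  if (length(miss))
    .stopInput("weight matrices lack reference types: ",
               paste(miss, collapse = ", "))
  list(w1 = weights@w1[types, types, drop = FALSE],
       w0 = weights@w0[types, types, drop = FALSE])
}

# same-cluster pair counts by (type, type): diagonal = within-type pairs,
# off-diagonal [j, j'] = cross-type co-clustered pairs (full matrix)
.sameClusterPairs <- function(counts) {
  M <- counts %*% t(counts)
  diag(M) <- (diag(M) - rowSums(counts)) / 2
  M
}

# all pairs by (type, type): diagonal = choose(n_j+, 2), off-diag n_j+ n_j'+
.totalPairs <- function(counts) {
  m <- rowSums(counts)
  Tm <- m %o% m
  diag(Tm) <- .choose2(m)
  Tm
}

# sum a symmetric per-type-pair score matrix over unordered type pairs
.pairSum <- function(S) sum(S[upper.tri(S, diag = TRUE)])

#' Rand index
#'
#' Proportion of cell pairs whose same/different-group relationship agrees
#' between clustering and reference: \code{(N11 + N00) / N}.
#'
#' @param x a \linkS4class{ContingencyTable}, or a pair-count vector as
#'   returned by \code{\link{pairCounts}}.
#' @return a number in [0, 1].
#' @export
randIndex <- function(x) {
  pc <- if (is(x, "ContingencyTable")) pairCounts(x) else x
  unname((pc["N11"] + pc["N00"]) / pc["N"])
}

#' Adjusted Rand index
#'
#' Rand index corrected for chance under the permutation null model with
#' fixed margins. With both partitions trivial (a single group each, or all
#' singletons on both sides) the correction denominator vanishes; the
#' conventional value 1 is returned since the partitions then agree exactly.
#'
#' @param ct a \linkS4class{ContingencyTable}.
#' @return a number \eqn{\le} 1.
#' @export
adjustedRandIndex <- function(ct) {
  stopifnot(is(ct, "ContingencyTable"))
  sumIdx <- sum(.choose2(ct@counts))
  sumRow <- sum(.choose2(rowMargins(ct)))
  sumCol <- sum(.choose2(colMargins(ct)))
  E <- sumRow * sumCol / .choose2(nCells(ct))
  denom <- (sumRow + sumCol) / 2 - E
  if (abs(denom) < .Machine$double.eps * 4) return(1)
  (sumIdx - E) / denom
}

#' Weighted agreement score S*
#'
#' Total score over all cell pairs, where a co-clustered pair of types
#' (j, j') contributes \code{w1[j, j']} and a separated pair \code{w0[j, j']}.
#' Computed in O(I J^2) from the contingency table rather than over the
#' n(n-1)/2 pairs. \code{mode = "RR"} scores the reference against itself,
#' the normalizing constant of the weighted Rand index (equal to
#' \code{choose(n, 2)} under canonical weights).
#'
#' @param ct a \linkS4class{ContingencyTable}.
#' @param weights a \linkS4class{ClusterWeights} covering the table's types.
#' @param mode \code{"CR"} (clustering vs reference) or \code{"RR"}.
#' @return the scalar S*.
#' @export
weightedAgreementScore <- function(ct, weights, mode = c("CR", "RR")) {
  stopifnot(is(ct, "ContingencyTable"), is(weights, "ClusterWeights"))
  mode <- match.arg(mode)
  w <- .alignWeights(ct, weights)
  counts <- ct@counts
  if (mode == "RR") {
    m <- rowMargins(ct)
    counts <- diag(m, nrow = length(m))
    dimnames(counts) <- list(names(m), names(m))
  }
  P1 <- .sameClusterPairs(counts)
  P0 <- .totalPairs(counts) - P1
  .pairSum(w$w1 * P1 + w$w0 * P0)
}

#' Weighted Rand index
#'
#' The hierarchy-aware Rand index \code{wRI = S*(C, R) / S*(R, R)}: the
#' weighted pairwise agreement of the clustering with the reference,
#' normalized by the reference's agreement with itself. Identity weights
#' recover the classical Rand index exactly; canonical weights keep the
#' value in [0, 1].
#'
#' @param ref,clust \linkS4class{CellPartition}s over the same cell ids, or
#'   \code{ref} may be a precomputed \linkS4class{ContingencyTable} (then
#'   \code{clust} is omitted).
#' @param weights a \linkS4class{ClusterWeights} over the reference types.
#' @return the wRI score.
#' @examples
#' ref <- CellPartition(c("A", "A", "B", "B"))
#' cl  <- CellPartition(c("1", "2", "1", "2"))
#' w1 <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' w0 <- matrix(c(.2, 1, 1, .2), 2, dimnames = dimnames(w1))
#' weightedRandIndex(ref, cl, ClusterWeights(w1, w0))  # 3.4 / 6
#' @export
weightedRandIndex <- function(ref, clust, weights) {
  ct <- if (is(ref, "ContingencyTable")) ref else buildContingency(ref, clust)
  sCR <- weightedAgreementScore(ct, weights, "CR")
  sRR <- weightedAgreementScore(ct, weights, "RR")
  if (sRR <= 0)
    .stopDegenerate("degenerate weights: S*(R, R) = 0")
  sCR / sRR
}

#' Weighted positive and negative predictive values
#'
#' Mean pair score among co-clustered pairs (wPPV) and among separated pairs
#' (wNPV). Under identity weights these are the classical predictive values
#' N11/N+1 and N00/N+0, and the Rand index is their pair-count-weighted
#' average. A side with no pairs (a single cluster, or all singletons) is
#' reported as \code{NA} with a warning rather than 0.
#'
#' @inheritParams weightedRandIndex
#' @return named numeric \code{c(wPPV, wNPV)}.
#' @export
weightedPredictiveValues <- function(ref, clust, weights) {
  ct <- if (is(ref, "ContingencyTable")) ref else buildContingency(ref, clust)
  w <- .alignWeights(ct, weights)
  P1 <- .sameClusterPairs(ct@counts)
  P0 <- .totalPairs(ct@counts) - P1
  n1 <- .pairSum(P1)
  n0 <- .pairSum(P0)
  wPPV <- if (n1 > 0) .pairSum(w$w1 * P1) / n1 else {
    warning("no co-clustered pairs: wPPV undefined"); NA_real_
  }
  wNPV <- if (n0 > 0) .pairSum(w$w0 * P0) / n0 else {
    warning("no separated pairs: wNPV undefined"); NA_real_
  }
  c(wPPV = wPPV, wNPV = wNPV)
}
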