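#' Accessors for CellPartition
#'
#' \code{cellIds} returns the cell identifiers, \code{cellLabels} the group
#' label of each cell (named by cell id), \code{groupLabels} the distinct
#' group labels in first-appearance order, \code{groupSizes} the number of
#' cells per group, and \code{nCells} the population size.
#'
#' @param x a \linkS4class{CellPartition}.
#' @return see description; \code{groupSizes} is named by group label.
#' @name CellPartition-accessors
#' @aliases cellIds cellLabels groupLabels groupSizes nCells
#'   cellIds,CellPartition-method cellLabels,CellPartition-method
#'   groupLabels,CellPartition-method groupSizes,CellPartition-method
#'   nCells,CellPartition-method
NULL

#' @rdname CellPartition-accessors
#' @export
setMethod("cellIds", "CellPartition", function(x) x@cellIds)

#' @rdname CellPartition-accessors
#' @export
setMethod("cellLabels", "CellPartition",
          function(x) setNames(x@labels, x@cellIds))

#' @rdname CellPartition-accessors
#' @export
setMethod("groupLabels", "CellPartition", function(x) unique(x@labels))

#' @rdname CellPartition-accessors
#' @export
setMethod("groupSizes", "CellPartition", function(x) {
  g <- unique(x@labels)
  setNames(tabulate(match(x@labels, g), length(g)), g)
})

#' @rdname CellPartition-accessors
#' @export
setMethod("nCells", "CellPartition", function(x) length(x@cellIds))

setMethod("show", "CellPartition", function(object) {
  g <- groupSizes(object)
  cat("CellPartition with", nCells(object), "cells in", length(g),
      "groups\n")
  cat("  groups:", paste0(names(g), " (", g, ")", collapse = ", "), "\n")
})

#' Cross-tabulate a clustering against a reference partition
#'
#' Builds the J x I contingency table counting cells by (reference type,
#' cluster). Cells are matched by id, so the two label tables may list the
#' cells in different orders; the two id sets must coincide exactly.
#'
#' @param ref reference \linkS4class{CellPartition} (J types).
#' @param clust clustering \linkS4class{CellPartition} (I clusters).
#' @return a \linkS4class{ContingencyTable}; rows follow the reference's
#'   first-appearance type order, columns the clustering's.
#' @examples
#' ref <- CellPartition(c("A", "A", "B", "B"))
#' cl  <- CellPartition(c("1", "2", "1", "2"))
#' tableCounts(buildContingency(ref, cl))
#' @export
buildContingency <- function(ref, clust) {
  stopifnot(is(ref, "CellPartition"), is(clust, "CellPartition"))
  onlyRef <- setdiff(ref@cellIds, clust@cellIds)
  onlyClust <- setdiff(clust@cellIds, ref@cellIds)
  if (length(onlyRef) || length(onlyClust))
    .stopInput("cell id sets differ between reference and clustering",
               if (length(onlyRef)) paste0("; only in reference: ",
                 paste(head(onlyRef, 5L), collapse = ", ")) else "",
               if (length(onlyClust)) paste0("; only in clustering: ",
                 paste(head(onlyClust, 5L), collapse = ", ")) else "")
  cl <- cellLabels(clust)[ref@cellIds]
  rlev <- unique(ref@labels)
  clev <- unique(clust@labels)
  counts <- matrix(0, length(rlev), length(clev),
                   dimnames = list(rlev, clev))
  for (k in seq_along(cl))
    counts[ref@labels[k], cl[k]] <- counts[ref@labels[k], cl[k]] + 1
  ContingencyTable(counts)
}

#' Accessors for ContingencyTable
#'
#' @param x a \linkS4class{ContingencyTable}.
#' @return \code{tableCounts}: the J x I count matrix; \code{rowMargins} /
#'   \code{colMargins}: named marginal totals; \code{nCells}: total count.
#' @name ContingencyTable-accessors
#' @aliases tableCounts rowMargins colMargins
#'   tableCounts,ContingencyTable-method rowMargins,ContingencyTable-method
#'   colMargins,ContingencyTable-method nCells,ContingencyTable-method
NULL

#' @rdname ContingencyTable-accessors
#' @export
setMethod("tableCounts", "ContingencyTable", function(x) x@counts)

#' @rdname ContingencyTable-accessors
#' @export
setMethod("rowMargins", "ContingencyTable", function(x) rowSums(x@counts))

#' @rdname ContingencyTable-accessors
#' @export
setMethod("colMargins", "ContingencyTable", function(x) colSums(x@counts))

#' @rdname ContingencyTable-accessors
#' @export
setMethod("nCells", "ContingencyTable", function(x) sum(x@counts))

setMethod("show", "ContingencyTable", function(object) {
  cat("ContingencyTable:", nrow(object@counts), "types x",
      ncol(object@counts), "clusters,", nCells(object), "cells\n")
  print(object@counts)
})

.choose2 <- function(x) x * (x - 1) / 2

#' Pairwise-relationship counts between two partitions
#'
#' Classifies the \eqn{\binom{n}{2}} cell pairs by whether each pair is
#' "related" (same group) in the reference and in the clustering: N11 related
#' in both, N10 related only in the reference, N01 related only in the
#' clustering, N00 separated in both.
#'
#' @param ct a \linkS4class{ContingencyTable}.
#' @return named numeric vector \code{c(N11, N10, N01, N00, N)}.
#' @examples
#' ref <- CellPartition(c("A", "A", "B", "B"))
#' pairCounts(buildContingency(ref, CellPartition(c("1", "2", "1", "2"))))
#' @export
pairCounts <- function(ct) {
  stopifnot(is(ct, "ContingencyTable"))
  n <- nCells(ct)
  N <- .choose2(n)
  N11 <- sum(.choose2(ct@counts))
  N1p <- sum(.choose2(rowMargins(ct)))
  Np1 <- sum(.choose2(colMargins(ct)))
  c(N11 = N11, N10 = N1p - N11, N01 = Np1 - N11,
    N00 = N - N1p - Np1 + N11, N = N)
}

#' Brute-force pairwise oracle over all cell pairs
#'
#' Literal O(n^2) enumeration of every cell pair, scoring each with the W1 /
#' W0 weight matrices. This is the reference computation the fast
#' contingency-table paths are checked against; it is intentionally naive
#' and refuses populations beyond \code{maxN} cells.
#'
#' @param ref,clust \linkS4class{CellPartition}s over the same cell ids.
#' @param weights a \linkS4class{ClusterWeights}; \code{NULL} uses identity
#'   weights, which reproduces the unweighted agreement score.
#' @param maxN hard cap on n (default 5000); beyond it use the
#'   contingency-table functions.
#' @return list with \code{sStar} (total weighted agreement), \code{s1Sum} /
#'   \code{s0Sum} (weighted sums over same- / different-cluster pairs),
#'   \code{n1} / \code{n0} (pair counts by clustering), and
#'   \code{pairCounts}.
#' @export
pairwiseOracle <- function(ref, clust, weights = NULL, maxN = 5000L) {
  stopifnot(is(ref, "CellPartition"), is(clust, "CellPartition"))
  n <- nCells(ref)
  if (n > maxN)
    .stopInput("pairwiseOracle is quadratic and capped at n = ", maxN,
               "; use the contingency-table functions for larger inputs")
  if (is.null(weights)) weights <- identityWeights(groupLabels(ref))
  stopifnot(is(weights, "ClusterWeights"))
  miss <- setdiff(groupLabels(ref), weights@typeLabels)
  if (length(miss))
    .stopInput("weight matrices lack reference types: ",
               paste(miss, collapse = ", "))
  cl <- cellLabels(clust)[ref@cellIds]
  if (anyNA(cl)) .stopInput("cell id sets differ between partitions")
  ti <- match(ref@labels, weights@typeLabels)
  w1 <- weights@w1; w0 <- weights@w0
  sStar <- s1 <- s0 <- 0; n11 <- n10 <- n01 <- n00 <- 0
  for (k1 in seq_len(n - 1L)) {
    for (k2 in (k1 + 1L):n) {
      same <- cl[k1] == cl[k2]
      score <- if (same) w1[ti[k1], ti[k2]] else w0[ti[k1], ti[k2]]
      sStar <- sStar + score
      sameRef <- ref@labels[k1] == ref@labels[k2]
      if (same) {
        s1 <- s1 + score
        if (sameRef) n11 <- n11 + 1 else n01 <- n01 + 1
      } else {
        s0 <- s0 + score
        if (sameRef) n10 <- n10 + 1 else n00 <- n00 + 1
      }
    }
  }
  list(sStar = sStar, s1Sum = s1, s0Sum = s0,
       n1 = n11 + n01, n0 = n10 + n00,
       pairCounts = c(N11 = n11, N10 = n10, N01 = n01, N00 = n00,
                      N = .choose2(n)))
}
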