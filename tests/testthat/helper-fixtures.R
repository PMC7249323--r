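# Shared fixtures and generators, all built in code.

# 4-cell weighted-Rand fixture: two types crossed over two clusters, with
# partial credit 0.5 for co-clustering A with B and splitting tolerance 0.2
fourCellFixture <- function() {
  types <- c("A", "B")
  w1 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(types, types))
  w0 <- matrix(c(0.2, 1, 1, 0.2), 2, dimnames = list(types, types))
  list(ref = CellPartition(c("A", "A", "B", "B")),
       clust = CellPartition(c("1", "2", "1", "2")),
       weights = ClusterWeights(w1, w0))
}

# 8-cell structured-entropy fixture: A1(2), A2(2), B(4), sibling pair
# (A1, A2) splitting at height 0.2 under a root at height 1
eightCellFixture <- function() {
  list(ref = CellPartition(rep(c("A1", "A2", "B"), c(2, 2, 4))),
       tree = ReferenceTree(ape::read.tree(
         text = "((A1:0.2,A2:0.2):0.8,B:1);")),
       coarse = CellPartition(rep(c("a", "b"), c(4, 4))))
}

# reference of sizes (2, 14, 14, 20) over a 2+2 sibling topology whose
# B-subtree splits at height hB and A-subtree at hA (root at 1)
sizedTreeSetup <- function(hB, hA = 0.5) {
  ref <- CellPartition(rep(c("A1", "A2", "B1", "B2"), c(2, 14, 14, 20)))
  tree <- ReferenceTree(ape::read.tree(text = sprintf(
    "((A1:%g,A2:%g):%g,(B1:%g,B2:%g):%g);", hA, hA, 1 - hA, hB, hB, 1 - hB)))
  list(ref = ref, tree = tree)
}

randomPartition <- function(n, k, prefix = "g") {
  # guarantee every group non-empty
  labs <- paste0(prefix, c(seq_len(k), sample.int(k, n - k, replace = TRUE)))
  CellPartition(sample(labs), cellIds = paste0("c", seq_len(n)))
}

randomPartitionPair <- function(n, J, I) {
  ref <- randomPartition(n, J, "t")
  clust <- CellPartition(
    paste0("k", c(seq_len(I), sample.int(I, n - I, replace = TRUE))),
    cellIds = ref@cellIds)
  list(ref = ref, clust = clust)
}

randomCanonicalWeights <- function(types) {
  J <- length(types)
  w1 <- matrix(runif(J * J), J, dimnames = list(types, types))
  w1[lower.tri(w1)] <- t(w1)[lower.tri(w1)]
  diag(w1) <- 1
  w0 <- matrix(1, J, J, dimnames = list(types, types))
  diag(w0) <- runif(J)
  ClusterWeights(w1, w0)
}

# random ultrametric tree over k leaf types, via hierarchical clustering of
# random points (guarantees valid heights)
randomReferenceTree <- function(k, labels = paste0("t", seq_len(k))) {
  x <- matrix(rnorm(k * 6), k, dimnames = list(labels, NULL))
  referenceTreeFromHclust(hclust(dist(x), method = "average"))
}

# random labelled partition over the leaves of a tree
randomTreePartition <- function(tree, n) {
  types <- typeLabels(tree)
  CellPartition(
    c(types, sample(types, n - length(types), replace = TRUE)),
    cellIds = paste0("c", seq_len(n)))
}
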