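ln2 <- log(2)

test_that("partition entropy matches closed forms", {
  expect_equal(partitionEntropy(CellPartition(c("A", "A", "A"))), 0)
  expect_equal(partitionEntropy(CellPartition(c("A", "A", "B", "B"))), ln2)
  expect_equal(partitionEntropy(
    CellPartition(rep(c("x", "y", "z"), c(1, 1, 2)))), 1.5 * ln2)
})

test_that("mutual information follows the contingency-table formula", {
  ref <- CellPartition(c("A", "A", "B", "B"))
  expect_equal(mutualInformation(buildContingency(ref,
    CellPartition(c("1", "1", "2", "2")))), ln2)
  expect_equal(mutualInformation(buildContingency(ref,
    CellPartition(c("1", "2", "1", "2")))), 0)
  fx <- eightCellFixture()
  expect_equal(mutualInformation(buildContingency(fx$ref, fx$coarse)), ln2)
})

test_that("NMI uses the arithmetic-mean normalization", {
  fx <- eightCellFixture()
  expect_equal(nmi(fx$ref, fx$ref), 1)
  expect_equal(nmi(fx$ref, fx$coarse), 0.8)
  balanced <- CellPartition(c("A", "A", "B", "B"))
  expect_equal(nmi(balanced, CellPartition(c("1", "2", "1", "2"))), 0)
  one <- CellPartition(rep("A", 4))
  expect_error(nmi(one, CellPartition(rep("1", 4))), "trivial")
})

test_that("tree cuts produce strictly nested partitions ending at the typing", {
  # forced topology: 3 leaves
  fx <- eightCellFixture()
  cuts <- cutPartitions(fx$tree, fx$ref)
  expect_length(cuts, 3)
  expect_equal(length(groupLabels(cuts[[1]])), 1L)
  expect_equal(unname(sort(groupSizes(cuts[[2]]))), c(4, 4))  # {A1+A2, B}
  expect_equal(unname(groupSizes(cuts[[2]])["A1+A2"]), 4)
  # the deepest cut is the leaf-level typing itself
  expect_equal(unname(cellLabels(cuts[[3]])), unname(cellLabels(fx$ref)))
  # caterpillar: each cut splits exactly one group
  tr <- ReferenceTree(ape::read.tree(
    text = "(((A:0.2,B:0.2):0.3,C:0.5):0.5,D:1);"))
  ref <- CellPartition(rep(c("A", "B", "C", "D"), each = 2))
  cuts <- cutPartitions(tr, ref)
  expect_length(cuts, 4)
  for (j in 1:3) {
    gj <- length(groupLabels(cuts[[j]]))
    expect_equal(length(groupLabels(cuts[[j + 1]])), gj + 1L)
    # refinement: cells together at level j+1 are together at level j
    lj <- cellLabels(cuts[[j]]); lj1 <- cellLabels(cuts[[j + 1]])
    expect_true(all(tapply(lj, lj1, function(x) length(unique(x))) == 1L))
  }
  expect_error(cutPartitions(tr, CellPartition(c("A", "Z", "Z", "B"))), "Z")
})

test_that("step weights are descending standardized heights with d1 = 1", {
  fx <- eightCellFixture()
  expect_equal(stepWeights(fx$tree), c(1, 0.2))
  scaled <- ReferenceTree(ape::read.tree(text = "((A1:1,A2:1):4,B:5);"))
  expect_equal(stepWeights(scaled), c(1, 0.2))   # scale invariance
  twoLeaf <- ReferenceTree(ape::read.tree(text = "(A:1,B:1);"))
  expect_equal(stepWeights(twoLeaf), 1)
})

test_that("structured entropy matches the 8-cell fixture and flat-tree limit", {
  fx <- eightCellFixture()
  expect_equal(structuredEntropy(fx$ref, fx$tree), 1.1 * ln2)
  # star tree: all d = 1, structured entropy equals plain entropy
  star <- ReferenceTree(ape::read.tree(text = "(A1:1,A2:1,B:1);"))
  expect_equal(stepWeights(star), c(1, 1))
  expect_equal(structuredEntropy(fx$ref, star), partitionEntropy(fx$ref))
})

test_that("structured conditional entropy brackets its limits", {
  fx <- eightCellFixture()
  expect_equal(structuredConditionalEntropy(fx$ref, fx$tree, fx$ref), 0)
  expect_equal(structuredConditionalEntropy(fx$ref, fx$tree, fx$coarse),
               0.1 * ln2)
  allOne <- CellPartition(rep("1", 8), cellIds = cellIds(fx$ref))
  expect_equal(structuredConditionalEntropy(fx$ref, fx$tree, allOne),
               structuredEntropy(fx$ref, fx$tree))
})

test_that("wMI and wNMI reproduce the 8-cell fixture and its limits", {
  fx <- eightCellFixture()
  expect_equal(weightedNMI(fx$ref, fx$tree, fx$ref)[["wNMI"]], 1)
  res <- weightedNMI(fx$ref, fx$tree, fx$coarse)
  expect_equal(res[["wMI"]], ln2)
  expect_equal(res[["wNMI"]], 12 / 11)   # above 1 by design, not clipped
  one <- CellPartition(rep("A1", 8))
  expect_error(weightedNMI(one, fx$tree, fx$coarse), "single-type")
})

test_that("nested-cut conditional entropies satisfy identity and chain rules", {
  set.seed(21)
  for (rep in 1:30) {
    J <- sample(3:7, 1)
    tree <- randomReferenceTree(J)
    ref <- randomTreePartition(tree, sample((J + 1):60, 1))
    cuts <- cutPartitions(tree, ref)
    H <- vapply(cuts, partitionEntropy, numeric(1))
    # entropy-difference route equals the direct per-group conditional sum
    for (j in seq_len(J - 1)) {
      direct <- scHierEval:::.condEntropyByCluster(
        cellLabels(cuts[[j + 1]]), cellLabels(cuts[[j]]))
      expect_equal(H[j + 1] - H[j], direct, tolerance = 1e-12)
    }
    # chain decomposition: steps sum to the leaf-level entropy
    expect_equal(sum(diff(H)), partitionEntropy(ref), tolerance = 1e-12)
  }
})

test_that("conditional entropy via joint identity equals per-cluster oracle", {
  set.seed(22)
  for (rep in 1:20) {
    pp <- randomPartitionPair(sample(6:60, 1), sample(2:5, 1), sample(2:5, 1))
    a <- cellLabels(pp$ref); b <- cellLabels(pp$clust)[cellIds(pp$ref)]
    expect_equal(scHierEval:::.condEntropy(a, b),
                 scHierEval:::.condEntropyByCluster(a, b), tolerance = 1e-12)
  }
})

test_that("unit step weights collapse (wMI, wNMI) onto (MI, NMI)", {
  set.seed(23)
  for (rep in 1:20) {
    J <- sample(3:6, 1)
    # star tree over J types: every d_j = 1
    nwk <- paste0("(", paste0("t", 1:J, ":1", collapse = ","), ");")
    star <- ReferenceTree(ape::read.tree(text = nwk))
    ref <- randomTreePartition(star, sample((J + 1):60, 1))
    clust <- randomPartition(nCells(ref), sample(2:6, 1), "k")
    clust <- CellPartition(cellLabels(clust), cellIds = cellIds(ref))
    res <- weightedNMI(ref, star, clust)
    ct <- buildContingency(ref, clust)
    expect_equal(res[["wMI"]], mutualInformation(ct), tolerance = 1e-12)
    expect_equal(res[["wNMI"]], nmi(ref, clust), tolerance = 1e-12)
  }
})

test_that("wMI is bounded by the structured entropy and H*(R|C) by refinement", {
  set.seed(24)
  for (rep in 1:15) {
    J <- sample(3:6, 1)
    tree <- randomReferenceTree(J)
    ref <- randomTreePartition(tree, sample(20:60, 1))
    clust <- CellPartition(
      cellLabels(randomPartition(nCells(ref), sample(2:4, 1), "k")),
      cellIds = cellIds(ref))
    hStar <- structuredEntropy(ref, tree)
    wmi <- weightedNMI(ref, tree, clust)[["wMI"]]
    expect_gte(wmi, -1e-12); expect_lte(wmi, hStar + 1e-12)
    # splitting one cluster never increases the unexplained entropy
    labs <- cellLabels(clust)
    big <- names(which.max(groupSizes(clust)))
    idx <- which(labs == big)
    labs[idx[seq_len(ceiling(length(idx) / 2))]] <- paste0(big, "_b")
    refined <- CellPartition(labs, cellIds = cellIds(ref))
    expect_lte(structuredConditionalEntropy(ref, tree, refined),
               structuredConditionalEntropy(ref, tree, clust) + 1e-12)
  }
})

test_that("normalized metrics are invariant to the logarithm base", {
  set.seed(25)
  tree <- randomReferenceTree(5)
  ref <- randomTreePartition(tree, 50)
  clust <- CellPartition(cellLabels(randomPartition(50, 3, "k")),
                         cellIds = cellIds(ref))
  expect_equal(nmi(ref, clust, base = 2), nmi(ref, clust), tolerance = 1e-12)
  expect_equal(weightedNMI(ref, tree, clust, base = 2)[["wNMI"]],
               weightedNMI(ref, tree, clust)[["wNMI"]], tolerance = 1e-12)
})

test_that("tied heights leave entropy sums invariant to cut order", {
  # same grouping expressed as one trifurcation vs tied binary splits
  multi <- ReferenceTree(ape::read.tree(text = "((A:0.5,B:0.5,C:0.5):0.5,D:1);"))
  binary <- ReferenceTree(ape::read.tree(
    text = "(((A:0.5,B:0.5):0,C:0.5):0.5,D:1);"))
  ref <- CellPartition(rep(c("A", "B", "C", "D"), c(2, 3, 4, 5)))
  clust <- CellPartition(rep(c("1", "2"), c(7, 7)), cellIds = cellIds(ref))
  expect_equal(stepWeights(multi), stepWeights(binary))
  expect_equal(structuredEntropy(ref, multi), structuredEntropy(ref, binary),
               tolerance = 1e-12)
  expect_equal(structuredConditionalEntropy(ref, multi, clust),
               structuredConditionalEntropy(ref, binary, clust),
               tolerance = 1e-12)
})
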