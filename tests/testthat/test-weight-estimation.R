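mkExpr <- function(mat, genes = paste0("g", seq_len(nrow(mat))),
                   cells = paste0("c", seq_len(ncol(mat)))) {
  dimnames(mat) <- list(genes, cells)
  mat
}

test_that("mean profiles average log1p expression per type", {
  expr <- mkExpr(cbind(c(0, 3, 7), c(0, 3, 7), c(1, 0, 2)))
  ref <- CellPartition(c("T1", "T1", "T2"), cellIds = paste0("c", 1:3))
  prof <- meanProfiles(expr, ref)
  expect_equal(prof["T1", ], log1p(c(0, 3, 7)), ignore_attr = TRUE)
  expect_equal(prof["T2", ], log1p(c(1, 0, 2)), ignore_attr = TRUE)
  expect_equal(attr(prof, "cellCounts"), c(T1 = 2L, T2 = 1L))
  expect_error(meanProfiles(expr, CellPartition(c("a", "b"),
    cellIds = c("c1", "cZ"))), "cZ")
})

test_that("mean profiles recover the generator's type means", {
  sim <- simulatePopulation(cellsPerType = 200, nGenes = 120, drift = 1,
                            noise = 0.4, seed = 31)
  prof <- meanProfiles(sim$expression, sim$labels)
  # log1p(round(exp(mu + eps))) concentrates near mu for mu >> 0; compare on
  # well-expressed genes where the rounding bias is negligible
  hi <- sim$typeProfiles["A", ] > 2
  expect_gt(cor(prof["A", hi], sim$typeProfiles["A", hi]), 0.98)
  expect_lt(mean(abs(prof["A", hi] - sim$typeProfiles["A", hi])), 0.12)
})

test_that("top variable genes are ranked by across-type variance, stably", {
  prof <- rbind(c(0, 0, 1, 2, 4), c(0, 1, 3, 5, 0), c(0, 2, 5, 8, 8))
  dimnames(prof) <- list(c("a", "b", "c"), paste0("g", 1:5))
  v <- apply(prof, 2, var)
  expect_equal(topVariableGenes(prof, 2), order(-v)[1:2])
  # the constant gene is never selected while varying genes remain
  expect_false(1L %in% topVariableGenes(prof, 4))
  expect_warning(all <- topVariableGenes(prof, 10), "exceeds")
  expect_length(all, 5)
  expect_error(topVariableGenes(prof[, 1, drop = FALSE], 2), "2 genes")
})

test_that("W1 is the clamped Pearson correlation of mean profiles", {
  prof <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4), C = c(4, 3, 2, 1))
  colnames(prof) <- paste0("g", 1:4)
  w1 <- estimateW1(prof)
  expect_equal(w1["A", "B"], 1)     # identical profiles
  expect_equal(w1["A", "C"], 0)     # r = -1 clamped to 0
  expect_equal(diag(w1), c(A = 1, B = 1, C = 1))
  flat <- rbind(A = rep(1, 4), B = c(1, 2, 3, 4))
  colnames(flat) <- paste0("g", 1:4)
  expect_error(estimateW1(flat), "A")
})

test_that("W0 diagonal measures within-type heterogeneity", {
  set.seed(32)
  tight <- matrix(rep(c(1, 5, 2, 8), 4), 4)          # identical cells
  noise <- matrix(rexp(4 * 50), 4)                   # unrelated cells
  expr <- mkExpr(cbind(tight, noise),
                 cells = paste0("c", 1:54))
  ref <- CellPartition(rep(c("tight", "noise"), c(4, 50)),
                       cellIds = paste0("c", 1:54))
  w0 <- estimateW0(expr, ref)
  expect_equal(w0["tight", "tight"], 0)
  expect_equal(w0["noise", "noise"], 1, tolerance = 0.1)
  expect_true(all(w0[upper.tri(w0)] == 1))
  # a single-cell type has no measurable heterogeneity
  ref1 <- CellPartition(c("solo", rep("noise", 53)),
                        cellIds = paste0("c", 1:54))
  expect_warning(w0s <- estimateW0(expr, ref1), "single cell")
  expect_equal(w0s["solo", "solo"], 0)
})

test_that("the to-mean heterogeneity variant behaves like the pairwise one", {
  sim <- simulatePopulation(cellsPerType = 40, nGenes = 100, seed = 33)
  g <- seq_len(100)
  w0p <- estimateW0(sim$expression, sim$labels, g)
  w0m <- estimateW0(sim$expression, sim$labels, g, method = "to-mean")
  expect_true(all(diag(w0m) >= 0 & diag(w0m) <= 1))
  # both should call the same types most heterogeneous
  expect_gt(cor(diag(w0p), diag(w0m), method = "spearman"), 0.5)
})

test_that("estimated weights are symmetric, in range, and tree-consistent", {
  sim <- simulatePopulation(cellsPerType = 100, nGenes = 300, drift = 1,
                            noise = 0.5, seed = 34)
  prof <- meanProfiles(sim$expression, sim$labels)
  genes <- topVariableGenes(prof, 200)
  w <- estimateWeights(sim$expression, sim$labels, nGenes = 200)
  w1 <- sameClusterWeights(w); w0 <- diffClusterWeights(w)
  expect_equal(w1, t(w1)); expect_equal(w0, t(w0))
  expect_true(all(w1 >= 0 & w1 <= 1) && all(w0 >= 0 & w0 <= 1))
  # sibling types (D, E) are the most similar pair in the default tree
  off <- w1; diag(off) <- NA
  expect_equal(which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1, ],
               c(row = 5L, col = 4L), ignore_attr = TRUE)
  # estimated tree recovers the generating topology
  rt <- buildReferenceTree(prof, genes)
  expect_equal(ape::dist.topo(ape::unroot(rt@tree),
                              ape::unroot(sim$tree@tree)), 0,
               ignore_attr = TRUE)
  expect_equal(max(treeHeights(rt)), 1)
  expect_equal(stepWeights(rt)[1], 1)
})

test_that("gene selection and weights are invariant to the log base", {
  sim <- simulatePopulation(cellsPerType = 30, nGenes = 80, seed = 35)
  profE <- meanProfiles(sim$expression, sim$labels)
  profTwo <- profE / log(2)      # log2(x + 1) = log1p(x) / log(2)
  expect_identical(topVariableGenes(profE, 40), topVariableGenes(profTwo, 40))
  g <- topVariableGenes(profE, 40)
  expect_equal(estimateW1(profE, g), estimateW1(profTwo, g),
               tolerance = 1e-12)
})

test_that("degenerate trees and tiny inputs are rejected", {
  prof <- rbind(A = c(1, 2), B = c(1, 2))
  colnames(prof) <- c("g1", "g2")
  expect_error(buildReferenceTree(prof), "identical")
  expect_error(buildReferenceTree(prof[1, , drop = FALSE]), "2 types")
  # J = 2 gives the single-split tree with d = 1
  prof2 <- rbind(A = c(0, 0), B = c(3, 4))
  colnames(prof2) <- c("g1", "g2")
  rt <- buildReferenceTree(prof2)
  expect_equal(stepWeights(rt), 1)
})

test_that("hclust conversion preserves relative merge heights exactly", {
  set.seed(36)
  x <- matrix(rnorm(40), 8, dimnames = list(paste0("t", 1:8), NULL))
  hc <- hclust(dist(x), method = "complete")
  rt <- referenceTreeFromHclust(hc)
  expect_equal(stepWeights(rt),
               sort(hc$height, decreasing = TRUE) / max(hc$height),
               tolerance = 1e-12)
})
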