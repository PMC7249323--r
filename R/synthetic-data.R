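#' Default five-type benchmark hierarchy
#'
#' A small ultrametric cell-type tree used as the default simulation
#' topology: two close sibling types (D, E), a moderately separated relative
#' (C), and a distant pair (A, B). Root height 1.
#'
#' @return a \linkS4class{ReferenceTree} with 5 leaves.
#' @export
defaultTypeTree <- function() {
  ReferenceTree(ape::read.tree(
    text = "((A:0.6,B:0.6):0.4,(C:0.45,(D:0.15,E:0.15):0.3):0.55);"))
}

.subSeeds <- function(seed, n) {
  if (is.null(seed)) .stopInput("a seed is required for reproducibility")
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a hierarchical cell population with known ground truth
#'
#' Generates an expression matrix whose cell-type structure follows a given
#' ultrametric tree. Type mean log-expression profiles evolve from a common
#' ancestor by independent Gaussian (Brownian-like) drift along each branch,
#' with per-gene variance \code{drift^2 * branch length}, so expected
#' expression distance between types tracks their tree distance. Cells are
#' then drawn around their type profile either by adding lognormal noise
#' and rounding (\code{model = "lognormal"}) or from a negative binomial
#' with the type mean and a stated dispersion (\code{model = "nb"}).
#'
#' A single seed drives three independent RNG streams (ancestral profile,
#' branch drift, cell noise), so e.g. regenerating with a different noise
#' level keeps the same type profiles.
#'
#' @param tree tree topology with branch lengths: a
#'   \linkS4class{ReferenceTree} or \code{ape::phylo}; default
#'   \code{\link{defaultTypeTree}}.
#' @param cellsPerType cells per type: a single count or a vector named by
#'   type (default 100).
#' @param nGenes number of genes (default 500).
#' @param drift per-unit-branch-length standard deviation of the mean
#'   log-profile drift (default 1); 0 makes all types identical in
#'   expectation.
#' @param noise within-type standard deviation of per-cell log expression
#'   (default 0.5); 0 makes all cells of a type identical under the
#'   lognormal model.
#' @param model count model, \code{"lognormal"} (rounded lognormal) or
#'   \code{"nb"} (negative binomial).
#' @param dispersion negative-binomial dispersion (size = 1/dispersion);
#'   ignored for the lognormal model.
#' @param baselineMean,baselineSD distribution of the ancestral mean log
#'   profile (defaults 1.5 and 1).
#' @param seed integer seed; mandatory.
#' @return list with \code{expression} (genes x cells matrix),
#'   \code{labels} (\linkS4class{CellPartition}), \code{tree} (the
#'   \linkS4class{ReferenceTree}), \code{typeProfiles} (true mean log
#'   profiles, types x genes), and \code{patristic} (true between-type tree
#'   distances).
#' @examples
#' sim <- simulatePopulation(cellsPerType = 20, nGenes = 50, seed = 1)
#' dim(sim$expression)
#' @export
simulatePopulation <- function(tree = defaultTypeTree(), cellsPerType = 100L,
                               nGenes = 500L, drift = 1, noise = 0.5,
                               model = c("lognormal", "nb"),
                               dispersion = 0.5, baselineMean = 1.5,
                               baselineSD = 1, seed) {
  model <- match.arg(model)
  tree <- ReferenceTree(tree)
  if (drift < 0 || noise < 0 || dispersion <= 0 || nGenes < 2L)
    .stopInput("scales must be non-negative, dispersion positive, nGenes >= 2")
  phy <- tree@tree
  types <- phy$tip.label
  nTip <- length(types)
  if (length(cellsPerType) == 1L)
    cellsPerType <- setNames(rep.int(as.integer(cellsPerType), nTip), types)
  cellsPerType <- cellsPerType[types]
  if (anyNA(cellsPerType) || any(cellsPerType < 1L))
    .stopInput("cellsPerType must give at least one cell for every type")
  seeds <- .subSeeds(seed, 3L)

  geneIds <- paste0("gene", seq_len(nGenes))
  set.seed(seeds[1])
  rootMu <- rnorm(nGenes, baselineMean, baselineSD)

  # drift the mean profile down every edge, root to leaves
  set.seed(seeds[2])
  nNode <- nTip + phy$Nnode
  mu <- matrix(NA_real_, nNode, nGenes)
  root <- nTip + 1L
  mu[root, ] <- rootMu
  edges <- phy$edge[order(ape::node.depth.edgelength(phy)[phy$edge[, 2]]), ,
                    drop = FALSE]
  elen <- phy$edge.length[order(ape::node.depth.edgelength(phy)[phy$edge[, 2]])]
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; child <- edges[e, 2]
    mu[child, ] <- mu[par, ] + rnorm(nGenes, 0, drift * sqrt(elen[e]))
  }
  typeProfiles <- mu[seq_len(nTip), , drop = FALSE]
  dimnames(typeProfiles) <- list(types, geneIds)

  set.seed(seeds[3])
  nCellsTotal <- sum(cellsPerType)
  cellIds <- paste0("cell", seq_len(nCellsTotal))
  labels <- rep(types, cellsPerType)
  expr <- matrix(0, nGenes, nCellsTotal, dimnames = list(geneIds, cellIds))
  col <- 0L
  for (j in seq_len(nTip)) {
    for (c in seq_len(cellsPerType[j])) {
      col <- col + 1L
      logx <- typeProfiles[j, ] + rnorm(nGenes, 0, noise)
      expr[, col] <- if (model == "lognormal") round(exp(logx))
                     else rnbinom(nGenes, mu = exp(logx),
                                  size = 1 / dispersion)
    }
  }
  list(expression = expr,
       labels = CellPartition(labels, cellIds = cellIds),
       tree = tree,
       typeProfiles = typeProfiles,
       patristic = ape::cophenetic.phylo(phy)[types, types])
}

# mrca height (above leaves) for every pair of leaf types
.mrcaHeights <- function(tree) {
  ape::cophenetic.phylo(tree@tree) / 2
}

#' Perturb a reference partition with a controlled clustering error
#'
#' Starts from a perfect clustering (one cluster per reference type) and
#' introduces one named error archetype, the building blocks for studying
#' how hierarchy-aware metrics react to different mistakes:
#' \describe{
#'   \item{merge_siblings}{moves \code{magnitude} cells of one type into the
#'     cluster of the tree-closest other type (lowest common-ancestor
#'     height).}
#'   \item{merge_distant}{the same move toward the tree-farthest type.}
#'   \item{split_type}{splits \code{magnitude} cells of the largest type
#'     into a new cluster.}
#'   \item{random_swap}{reassigns \code{magnitude} random cells to a random
#'     different cluster (requires \code{seed}).}
#' }
#' For the merge modes the auto-picked pair can be overridden with
#' \code{fromType} / \code{toType}. Without a seed, the cells moved are the
#' first \code{magnitude} cells of the source type in cell-id order, so the
#' perturbation is deterministic.
#'
#' @param ref reference \linkS4class{CellPartition}.
#' @param mode one of the archetypes above.
#' @param tree \linkS4class{ReferenceTree}, required by the merge modes.
#' @param magnitude number of cells moved; 0 returns the reference unchanged.
#' @param fromType,toType optional explicit source / destination types for
#'   the merge modes.
#' @param seed optional seed for random cell selection; required for
#'   \code{random_swap}.
#' @return a clustering \linkS4class{CellPartition}.
#' @export
perturbClustering <- function(ref, mode = c("merge_siblings", "merge_distant",
                                            "split_type", "random_swap"),
                              tree = NULL, magnitude = 0L,
                              fromType = NULL, toType = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(ref, "CellPartition"))
  if (magnitude == 0L) return(ref)
  labels <- ref@labels
  types <- groupLabels(ref)
  if (mode %in% c("merge_siblings", "merge_distant")) {
    if (length(types) < 2L)
      .stopInput("merge modes need at least 2 reference types")
    if (is.null(fromType) || is.null(toType)) {
      if (is.null(tree))
        .stopInput("merge modes need a reference tree (or explicit ",
                   "fromType/toType)")
      tree <- ReferenceTree(tree)
      h <- .mrcaHeights(tree)[types, types]
      h[lower.tri(h, diag = TRUE)] <- NA
      pick <- which(if (mode == "merge_siblings") h == min(h, na.rm = TRUE)
                    else h == max(h, na.rm = TRUE), arr.ind = TRUE)[1, ]
      toType <- types[pick["row"]]
      fromType <- types[pick["col"]]
    }
    if (!all(c(fromType, toType) %in% types))
      .stopInput("fromType/toType must be reference types")
    src <- which(labels == fromType)
    if (magnitude > length(src))
      .stopInput("magnitude exceeds the ", length(src), " cells of type '",
                 fromType, "'")
    move <- if (is.null(seed)) src[seq_len(magnitude)] else {
      set.seed(as.integer(seed)); sample(src, magnitude)
    }
    labels[move] <- toType
  } else if (mode == "split_type") {
    if (is.null(fromType))
      fromType <- names(which.max(groupSizes(ref)))
    src <- which(labels == fromType)
    if (magnitude > length(src) - 1L)
      .stopInput("magnitude must leave at least one cell in type '",
                 fromType, "'")
    move <- if (is.null(seed)) src[seq_len(magnitude)] else {
      set.seed(as.integer(seed)); sample(src, magnitude)
    }
    labels[move] <- paste0(fromType, "_split")
  } else {                                         # random_swap
    if (is.null(seed))
      .stopInput("random_swap requires a seed")
    if (length(types) < 2L)
      .stopInput("random_swap needs at least 2 groups")
    set.seed(as.integer(seed))
    move <- sample(length(labels), magnitude)
    for (k in move)
      labels[k] <- sample(setdiff(types, labels[k]), 1L)
  }
  CellPartition(labels, cellIds = ref@cellIds)
}
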