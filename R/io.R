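.delimFor <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read and write cell label tables
#'
#' Label files are two-column delimited tables with header
#' \code{cell_id,label} (TSV accepted, chosen by extension). A single-column
#' variant holding only labels is accepted behind \code{positional = TRUE},
#' in which case cells are matched by position and given ids
#' \code{cell1..celln}.
#'
#' @param path file path.
#' @param positional accept a single "label" column with positional ids.
#' @return \code{readLabels}: a \linkS4class{CellPartition}.
#' @export
readLabels <- function(path, positional = FALSE) {
  if (!file.exists(path)) .stopInput("label file not found: ", path)
  df <- read.csv(path, sep = .delimFor(path), colClasses = "character",
                 check.names = FALSE)
  if (positional) {
    if (ncol(df) != 1L)
      .stopInput(path, ": positional label files must have exactly one ",
                 "column, found ", ncol(df))
    return(CellPartition(df[[1]]))
  }
  need <- c("cell_id", "label")
  if (!all(need %in% names(df)))
    .stopInput(path, ": expected columns 'cell_id' and 'label', found: ",
               paste(names(df), collapse = ", "))
  bad <- which(df$cell_id == "" | df$label == "")
  if (length(bad))
    .stopInput(path, ": empty cell_id/label at data line(s) ",
               paste(head(bad, 5L), collapse = ", "))
  dup <- which(duplicated(df$cell_id))
  if (length(dup))
    .stopInput(path, ": duplicated cell ids at data line(s) ",
               paste(head(dup, 5L), collapse = ", "), " (",
               paste(head(unique(df$cell_id[dup]), 5L), collapse = ", "), ")")
  CellPartition(df$label, cellIds = df$cell_id)
}

#' @param p a \linkS4class{CellPartition}.
#' @rdname readLabels
#' @export
writeLabels <- function(p, path) {
  stopifnot(is(p, "CellPartition"))
  write.csv(data.frame(cell_id = p@cellIds, label = p@labels),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.readWeightMatrix <- function(path) {
  if (!file.exists(path)) .stopInput("weight file not found: ", path)
  df <- read.csv(path, sep = .delimFor(path), check.names = FALSE)
  types <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!setequal(types, colnames(m)) || anyDuplicated(types))
    .stopInput(path, ": header types and first-column types must match; ",
               "missing column(s): ",
               paste(setdiff(types, colnames(m)), collapse = ", "))
  rownames(m) <- types
  m <- m[, types, drop = FALSE]
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    .stopInput(path, ": missing entries, e.g. (",
               types[bad[1, 1]], ", ", types[bad[1, 2]], ")")
  }
  m
}

#' Read and write W1/W0 weight matrices
#'
#' Each matrix is a CSV with cell-type names as both the header row and the
#' first column; every entry must be present. \code{readClusterWeights}
#' assembles the pair into a \linkS4class{ClusterWeights}.
#'
#' @param w1Path,w0Path file paths for the two matrices.
#' @param canonical passed to \code{\link{ClusterWeights}}.
#' @return a \linkS4class{ClusterWeights}.
#' @export
readClusterWeights <- function(w1Path, w0Path, canonical = TRUE) {
  w1 <- .readWeightMatrix(w1Path)
  w0 <- .readWeightMatrix(w0Path)
  if (!setequal(rownames(w1), rownames(w0)))
    .stopInput("w1 and w0 cover different type sets")
  ClusterWeights(w1, w0[rownames(w1), rownames(w1)], canonical = canonical)
}

#' @param w a \linkS4class{ClusterWeights}.
#' @rdname readClusterWeights
#' @export
writeClusterWeights <- function(w, w1Path, w0Path) {
  stopifnot(is(w, "ClusterWeights"))
  for (pair in list(list(w@w1, w1Path), list(w@w0, w0Path))) {
    df <- data.frame(type = rownames(pair[[1]]), pair[[1]],
                     check.names = FALSE)
    write.csv(df, pair[[2]], row.names = FALSE, quote = FALSE)
  }
  invisible(c(w1Path, w0Path))
}

#' Read and write the reference tree as Newick
#'
#' Branch lengths are required; node heights are reconstructed as the leaf
#' depth minus the root-to-node depth, with an ultrametric check.
#'
#' @param path Newick file path.
#' @param tol ultrametric tolerance passed to \code{\link{ReferenceTree}}.
#' @return a \linkS4class{ReferenceTree}.
#' @export
readReferenceTree <- function(path, tol = 1e-6) {
  if (!file.exists(path)) .stopInput("tree file not found: ", path)
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) .stopInput(path, ": not parseable ",
                                                 "Newick: ", conditionMessage(e)))
  if (is.null(phy)) .stopInput(path, ": not parseable Newick")
  ReferenceTree(phy, tol = tol)
}

#' @param tree a \linkS4class{ReferenceTree}.
#' @rdname readReferenceTree
#' @export
writeReferenceTree <- function(tree, path) {
  tree <- ReferenceTree(tree)
  ape::write.tree(tree@tree, file = path, digits = 15)
  invisible(path)
}

#' Read and write expression matrices
#'
#' Dense CSV/TSV (first column gene ids, header cell ids) or MatrixMarket
#' \code{.mtx} with one-id-per-line \code{genes}/\code{cells} sidecar files.
#'
#' @param path matrix file; \code{.mtx} triggers the sparse route.
#' @param genesPath,cellsPath sidecar id files, required for \code{.mtx}.
#' @return \code{readExpression}: genes x cells matrix (sparse for mtx).
#' @export
readExpression <- function(path, genesPath = NULL, cellsPath = NULL) {
  if (!file.exists(path)) .stopInput("expression file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genesPath) || is.null(cellsPath))
      .stopInput("MatrixMarket input needs genesPath and cellsPath sidecars")
    m <- Matrix::readMM(path)
    genes <- readLines(genesPath)
    cells <- readLines(cellsPath)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      .stopInput("sidecar lengths (", length(genes), " genes, ",
                 length(cells), " cells) do not match matrix dimensions ",
                 nrow(m), " x ", ncol(m))
    dimnames(m) <- list(genes, cells)
    return(.checkExpr(m))
  }
  df <- read.csv(path, sep = .delimFor(path), check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  .checkExpr(m)
}

#' @param expr genes x cells matrix with dimnames.
#' @rdname readExpression
#' @export
writeExpression <- function(expr, path, genesPath = NULL, cellsPath = NULL) {
  expr <- .checkExpr(expr)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genesPath) || is.null(cellsPath))
      .stopInput("MatrixMarket output needs genesPath and cellsPath")
    Matrix::writeMM(methods::as(methods::as(expr, "CsparseMatrix"),
                                "generalMatrix"), path)
    writeLines(rownames(expr), genesPath)
    writeLines(colnames(expr), cellsPath)
  } else {
    df <- data.frame(gene_id = rownames(expr), as.matrix(expr),
                     check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a MetricReport as JSON
#'
#' Full double precision; the JSON file is the canonical machine-readable
#' output (the printed table rounds to 3 decimals for display only).
#'
#' @param report a \linkS4class{MetricReport}.
#' @param path output path.
#' @export
writeMetricReport <- function(report, path) {
  stopifnot(is(report, "MetricReport"))
  jsonlite::write_json(
    list(metrics = as.list(report@metrics),
         pair_counts = as.list(report@pairCounts),
         provenance = report@provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
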