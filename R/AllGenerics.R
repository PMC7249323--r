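#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @export
setGeneric("tableCounts", function(x) standardGeneric("tableCounts"))

#' @export
setGeneric("rowMargins", function(x) standardGeneric("rowMargins"))

#' @export
setGeneric("colMargins", function(x) standardGeneric("colMargins"))

#' @export
setGeneric("sameClusterWeights", function(x) standardGeneric("sameClusterWeights"))

#' @export
setGeneric("diffClusterWeights", function(x) standardGeneric("diffClusterWeights"))

#' @export
setGeneric("typeLabels", function(x) standardGeneric("typeLabels"))

#' @export
setGeneric("treeHeights", function(x) standardGeneric("treeHeights"))

#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
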