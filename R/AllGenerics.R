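# Generics for the package's S4 classes. Accessors are exported; slot access
# is internal.

#' @export
setGeneric("snpCalls", function(x) standardGeneric("snpCalls"))

#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @export
setGeneric("parseReport", function(x) standardGeneric("parseReport"))

#' @export
setGeneric("geneAssignments", function(x) standardGeneric("geneAssignments"))

#' @export
setGeneric("snpDistances", function(x) standardGeneric("snpDistances"))

#' @export
setGeneric("assignmentTies", function(x) standardGeneric("assignmentTies"))

#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @export
setGeneric("edgeProvenance", function(x) standardGeneric("edgeProvenance"))

#' @export
setGeneric("graphMeta", function(x) standardGeneric("graphMeta"))

#' @export
setGeneric("filterEdgesByWeight",
           function(x, tau) standardGeneric("filterEdgesByWeight"))

#' @export
setGeneric("nodeDegree",
           function(x, mergeMultiEdges = FALSE) standardGeneric("nodeDegree"))

#' @export
setGeneric("assignNodeColors",
           function(x, palette = defaultNodePalette())
             standardGeneric("assignNodeColors"))

#' @export
setGeneric("exportGraph",
           function(x, path, format = c("graphml", "dot"))
             standardGeneric("exportGraph"))
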