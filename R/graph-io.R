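# Graph serialization: GraphML and Graphviz DOT via igraph, plus a plain
# edge-list writer and a GraphML importer for round-trip checks.

#' Convert an AssocGraph to an igraph object
#'
#' Undirected multigraph; vertices carry `gene`, `colored`, `color` and
#' `degree` attributes, edges carry `weight`, `color_gene` and `cis`.
#'
#' @param graph an [AssocGraph-class].
#' @return an [igraph::igraph] object.
#' @export
asIgraph <- function(graph) {
  nt <- nodeTable(graph)
  vertices <- data.frame(name = nt$gene, gene = nt$gene,
                         colored = nt$colored,
                         color = ifelse(is.na(nt$color), "", nt$color),
                         degree = nt$degree, stringsAsFactors = FALSE)
  e <- edgeTable(graph)
  edges <- data.frame(from = e$gene_a, to = e$gene_b,
                      weight = as.numeric(e$weight),
                      color_gene = e$color_gene, cis = e$cis,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' @describeIn AssocGraph-class write the graph as GraphML or Graphviz DOT.
#'   Every node carries `gene`, `colored`, `color` and `degree` attributes,
#'   every edge `weight`, `color_gene` and `cis`; multi-edges are preserved
#'   as distinct edge records.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @aliases exportGraph
#' @export
setMethod("exportGraph", "AssocGraph",
          function(x, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- asIgraph(x)
  suppressWarnings(igraph::write_graph(g, path, format = format))
  invisible(path)
})

#' Re-read an exported GraphML file
#'
#' Returns the node and edge attribute tables, canonically ordered, for
#' comparison against [nodeTable()]/[edgeTable()] output.
#'
#' @param path a GraphML file written by [exportGraph()].
#' @return list with data.frames `nodes` (`gene`, `colored`, `color`,
#'   `degree`) and `edges` (`gene_a`, `gene_b`, `color_gene`, `weight`,
#'   `cis`).
#' @export
importGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  nodes <- data.frame(gene = va$gene, colored = as.logical(va$colored),
                      color = ifelse(va$color == "", NA_character_, va$color),
                      degree = as.integer(va$degree),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$gene), , drop = FALSE]
  rownames(nodes) <- NULL
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el)) {
    edges <- data.frame(gene_a = pmin(el$from, el$to),
                        gene_b = pmax(el$from, el$to),
                        color_gene = el$color_gene,
                        weight = as.integer(el$weight),
                        cis = as.logical(el$cis), stringsAsFactors = FALSE)
    edges <- edges[order(edges$gene_a, edges$gene_b, edges$color_gene), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        color_gene = character(), weight = integer(),
                        cis = logical(), stringsAsFactors = FALSE)
  }
  list(nodes = nodes, edges = edges)
}

#' Write the edge list as a tab-separated table
#' @param graph an [AssocGraph-class].
#' @param path output file.
#' @export
writeEdgeList <- function(graph, path) {
  e <- edgeTable(graph)
  writeTsvLines("gene_a\tgene_b\tcolor_gene\tweight\tcis",
                if (nrow(e)) paste(e$gene_a, e$gene_b, e$color_gene,
                                   e$weight, e$cis, sep = "\t")
                else character(),
                path)
}
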