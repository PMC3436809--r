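# Construction and filtering of the gene-gene association multigraph.

#' Build the association gene network from SNP-pair results
#'
#' For every pair record with `p < alpha`, the two SNPs are mapped to their
#' genes (g_i, g_j) and the trait gene g_k becomes the edge color: the edge
#' keyed by the unordered endpoints \{g_i, g_j\} plus g_k gains one unit of
#' weight per distinct canonical SNP pair. Self-loops (both partners mapping
#' to the same gene) are allowed. Pairs containing an unassigned SNP are
#' skipped and counted. The node set is the full gene locus table, isolated
#' genes included; a gene is colored iff at least one edge carries it as
#' color gene. Edges whose color gene is one of their endpoints are flagged
#' `cis` (a nearby-gene effect); all others represent trans effects.
#'
#' Thresholding is strict (`p < alpha`); pass `inclusive = TRUE` for
#' `p <= alpha`.
#'
#' @param pairs data.frame from [readPairResults()] or [twoLocusScan()].
#' @param map a [SnpGeneMap-class] from [assignSnpsToGenes()].
#' @param loci gene loci (`GRanges` or data.frame); defines the node set.
#' @param alpha pair significance threshold (default 0.05).
#' @param inclusive use `p <= alpha` instead of strict `<`.
#' @return an [AssocGraph-class].
#' @examples
#' loci <- data.frame(gene = c("A", "B", "C", "D"), chrom = "chr1",
#'                    start = c(1, 101, 201, 301), end = c(100, 200, 300, 400))
#' snps <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "chr1",
#'                    pos = c(50L, 150L, 160L))
#' map <- assignSnpsToGenes(snps, loci)
#' pairs <- data.frame(snp_a = c("s1", "s1", "s1"),
#'                     snp_b = c("s2", "s3", "s2"),
#'                     trait_gene = c("C", "C", "D"), p = c(.01, .02, .01))
#' edgeTable(buildAssociationGraph(pairs, map, loci))
#' @export
buildAssociationGraph <- function(pairs, map, loci, alpha = 0.05,
                                  inclusive = FALSE) {
  stopifnot(is(map, "SnpGeneMap"), alpha > 0, alpha <= 1)
  lociDf <- lociAsDataFrame(loci)
  nodes <- sort(unique(lociDf$gene))
  badTrait <- setdiff(unique(pairs$trait_gene), nodes)
  if (length(badTrait))
    stop("trait gene(s) absent from locus table: ",
         paste(badTrait, collapse = ", "))
  asn <- geneAssignments(map)
  sig <- if (inclusive) pairs$p <= alpha else pairs$p < alpha
  sigPairs <- pairs[sig, , drop = FALSE]
  gA <- unname(asn[sigPairs$snp_a])
  gB <- unname(asn[sigPairs$snp_b])
  mapped <- !is.na(gA) & !is.na(gB)
  nSkipped <- sum(!mapped)
  gA <- gA[mapped]; gB <- gB[mapped]
  sp <- sigPairs[mapped, , drop = FALSE]
  pairId <- canonicalPairKey(sp$snp_a, sp$snp_b)
  # one contribution per distinct canonical SNP pair and trait
  dup <- duplicated(paste(pairId, sp$trait_gene, sep = "\r"))
  gA <- gA[!dup]; gB <- gB[!dup]
  sp <- sp[!dup, , drop = FALSE]; pairId <- pairId[!dup]
  ga <- pmin(gA, gB); gb <- pmax(gA, gB)
  key <- paste(ga, gb, sp$trait_gene, sep = "\r")
  prov <- split(pairId, key)
  ord <- !duplicated(key)
  edges <- data.frame(gene_a = ga[ord], gene_b = gb[ord],
                      color_gene = sp$trait_gene[ord],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b, edges$color_gene), ,
                 drop = FALSE]
  keyOrd <- paste(edges$gene_a, edges$gene_b, edges$color_gene, sep = "\r")
  prov <- prov[keyOrd]
  edges$weight <- as.integer(unname(lengths(prov)))
  edges$cis <- edges$color_gene == edges$gene_a |
    edges$color_gene == edges$gene_b
  rownames(edges) <- NULL
  colored <- stats::setNames(nodes %in% edges$color_gene, nodes)
  colors <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  new("AssocGraph", nodes = nodes, colored = colored, colors = colors,
      edges = edges, provenance = prov,
      meta = list(nPairsIn = nrow(pairs), nSignificant = sum(sig),
                  nSkippedUnassigned = nSkipped, alpha = alpha))
}

#' @describeIn AssocGraph-class keep only edges with `weight >= tau`. All
#'   nodes and their colored status are retained: the threshold filters the
#'   display, not the semantics.
#' @param tau minimum edge weight (>= 0).
#' @aliases filterEdgesByWeight
#' @export
setMethod("filterEdgesByWeight", "AssocGraph", function(x, tau) {
  stopifnot(tau >= 0)
  keep <- x@edges$weight >= tau
  edges <- x@edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  keys <- paste(edges$gene_a, edges$gene_b, edges$color_gene, sep = "\r")
  meta <- x@meta
  meta$tau <- tau
  initialize(x, edges = edges, provenance = x@provenance[keys], meta = meta)
})

#' @describeIn AssocGraph-class per-gene degree: the number of edges with the
#'   gene as an endpoint. Multi-edges (same endpoints, different color) count
#'   separately unless `mergeMultiEdges = TRUE`; a self-loop counts once.
#' @param mergeMultiEdges collapse multi-edges before counting?
#' @aliases nodeDegree
#' @export
setMethod("nodeDegree", "AssocGraph", function(x, mergeMultiEdges = FALSE) {
  e <- x@edges
  if (mergeMultiEdges && nrow(e))
    e <- e[!duplicated(paste(e$gene_a, e$gene_b, sep = "\r")), , drop = FALSE]
  deg <- stats::setNames(integer(length(x@nodes)), x@nodes)
  if (nrow(e)) {
    # count each edge once per distinct endpoint (self-loop -> 1)
    tab <- table(c(e$gene_a, e$gene_b[e$gene_a != e$gene_b]))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
})

#' Filter single-locus results to the highly significant SNP set
#'
#' Returns the SNPs having, for at least one trait gene, a regression
#' r-squared strictly above `r2Min` and a p-value strictly below `pMax`
#' (defaults: r2 > 0.1 and p < 0.05).
#'
#' @param results data.frame from [readSingleLocusResults()] or
#'   [singleLocusScan()].
#' @param r2Min,pMax thresholds in `[0, 1]`.
#' @return character vector of SNP ids.
#' @export
significantSingleLocusSnps <- function(results, r2Min = 0.1, pMax = 0.05) {
  stopifnot(r2Min >= 0, r2Min <= 1, pMax >= 0, pMax <= 1)
  hit <- results$r2 > r2Min & results$p < pMax
  sort(unique(results$snp_id[hit]))
}

#' Keep only SNP pairs with at least one partner in a SNP set
#' @param pairs data.frame of pair results.
#' @param keep character vector of SNP ids.
#' @return the retained subset of `pairs`.
#' @export
restrictPairsToSnpSet <- function(pairs, keep) {
  out <- pairs[pairs$snp_a %in% keep | pairs$snp_b %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distinct SNPs occurring in a pair list
#' @param pairs data.frame of pair results.
#' @return sorted character vector of SNP ids.
#' @export
snpsInPairs <- function(pairs) {
  sort(unique(c(pairs$snp_a, pairs$snp_b)))
}

#' Count pairs containing each focus SNP
#' @param pairs data.frame of pair results.
#' @param focus SNP ids to count for.
#' @return named integer vector (0 for focus SNPs in no pair).
#' @export
pairsPerSnp <- function(pairs, focus) {
  counts <- table(factor(c(pairs$snp_a, pairs$snp_b), levels = focus))
  stats::setNames(as.integer(counts), focus)
}

#' Default categorical node palette
#'
#' Ten distinguishable hues; roughly the practical limit for categorical
#' color coding of nodes.
#' @return character vector of 10 hex colors.
#' @export
defaultNodePalette <- function() {
  c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
    "#A65628", "#F781BF", "#17BECF", "#BCBD22", "#66C2A5")
}

#' @describeIn AssocGraph-class give every colored node a concrete palette
#'   color, assigned in alphabetical gene order; uncolored nodes become gray.
#'   If the palette is exhausted it cycles, with a warning.
#' @param palette ordered character vector of colors.
#' @aliases assignNodeColors
#' @export
setMethod("assignNodeColors", "AssocGraph",
          function(x, palette = defaultNodePalette()) {
  stopifnot(length(palette) >= 1L)
  colors <- stats::setNames(rep("#BEBEBE", length(x@nodes)), x@nodes)
  coloredGenes <- sort(x@nodes[x@colored])
  if (length(coloredGenes) > length(palette))
    warning(length(coloredGenes), " colored nodes but only ",
            length(palette), " palette colors; colors will repeat")
  if (length(coloredGenes))
    colors[coloredGenes] <-
      rep_len(palette, length(coloredGenes))
  initialize(x, colors = colors)
})
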