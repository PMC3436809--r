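#' @import methods
#' @importClassesFrom S4Vectors DataFrame
NULL

#' GenotypeMatrix: canonical per-patient allele calls
#'
#' Patients x SNPs grid of canonical unordered allele pairs. Calls are stored
#' as two-character strings with alleles in alphabetical order (`"AC"`), or
#' `NA` for a missing call, so genotype comparison is phase-free. Row names
#' are patient ids, column names SNP ids. `snpInfo` carries one row per SNP
#' (`snp_id`, `chrom`, `pos`, and `ref` once a reference table is attached);
#' coordinates are `NA` when the SNP id does not encode a position.
#'
#' @slot calls character matrix, patients in rows, SNPs in columns.
#' @slot snpInfo [S4Vectors::DataFrame] of per-SNP metadata.
#' @slot parseReport list with counts `nMissing` and `nUnparseable`
#'   accumulated while reading.
#' @seealso [readGenotypeTable()], [snpCalls()], [snpInfo()]
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(calls = "matrix", snpInfo = "DataFrame", parseReport = "list"))

setValidity("GenotypeMatrix", function(object) {
  calls <- object@calls
  msgs <- character()
  if (!is.character(calls)) msgs <- c(msgs, "calls must be a character matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    msgs <- c(msgs, "calls must have patient row names and SNP column names")
  if (anyDuplicated(rownames(calls))) msgs <- c(msgs, "duplicate patient ids")
  if (anyDuplicated(colnames(calls))) msgs <- c(msgs, "duplicate SNP ids")
  if (nrow(object@snpInfo) != ncol(calls))
    msgs <- c(msgs, "snpInfo rows must match SNP columns")
  vals <- calls[!is.na(calls)]
  if (length(vals)) {
    bad <- !grepl("^[ACGT]{2}$", vals) |
      substr(vals, 1L, 1L) > substr(vals, 2L, 2L)
    if (any(bad)) msgs <- c(msgs, "non-canonical genotype calls present")
  }
  if (length(msgs)) msgs else TRUE
})

#' SnpGeneMap: nearest-gene assignment of SNPs
#'
#' Maps every SNP to its closest gene: distance 0 if the SNP lies inside the
#' gene locus, otherwise the minimum of the distances to the locus boundaries
#' among genes on the same chromosome. SNPs with no same-chromosome gene (or
#' no usable coordinate) are unassigned (`NA`).
#'
#' @slot assignments named character vector, SNP id -> gene name or `NA`.
#' @slot distances named integer vector, SNP id -> distance in bp (0 inside).
#' @slot ties data.frame logging tie-broken assignments.
#' @seealso [assignSnpsToGenes()]
#' @exportClass SnpGeneMap
setClass("SnpGeneMap",
  representation(assignments = "character", distances = "integer",
                 ties = "data.frame"))

setValidity("SnpGeneMap", function(object) {
  msgs <- character()
  if (!identical(names(object@assignments), names(object@distances)))
    msgs <- c(msgs, "assignments and distances must share SNP names")
  if (anyDuplicated(names(object@assignments)))
    msgs <- c(msgs, "duplicate SNP ids in map")
  d <- object@distances
  if (any(!is.na(d) & d < 0L)) msgs <- c(msgs, "negative distances")
  if (length(msgs)) msgs else TRUE
})

#' AssocGraph: the gene-gene association multigraph
#'
#' Genes are nodes; every significant SNP pair contributes to one edge keyed
#' by the unordered endpoint genes of its two SNPs plus the trait gene whose
#' expression it is associated with (the edge "color"). Edge weight is the
#' number of distinct canonical SNP pairs behind the key, and `provenance`
#' retains those pairs. A node is *colored* iff at least one edge carries it
#' as color gene; all other nodes are drawn gray. Colored status is computed
#' on the full graph and deliberately preserved by display filtering
#' ([filterEdgesByWeight()]).
#'
#' @slot nodes character vector of gene names (all genes of the locus table).
#' @slot colored named logical per node.
#' @slot colors named character per node; concrete colors after
#'   [assignNodeColors()], `NA` before.
#' @slot edges data.frame with columns `gene_a`, `gene_b` (sorted so
#'   `gene_a <= gene_b`), `color_gene`, `weight`, `cis` (color gene is one of
#'   the endpoints).
#' @slot provenance named list, edge key -> character vector of canonical
#'   SNP-pair ids.
#' @slot meta list of construction counters (input pairs, significant pairs,
#'   pairs skipped for unassigned SNPs, alpha, tau).
#' @seealso [buildAssociationGraph()], [exportGraph()]
#' @exportClass AssocGraph
setClass("AssocGraph",
  representation(nodes = "character", colored = "logical",
                 colors = "character", edges = "data.frame",
                 provenance = "list", meta = "list"))

setValidity("AssocGraph", function(object) {
  msgs <- character()
  e <- object@edges
  need <- c("gene_a", "gene_b", "color_gene", "weight", "cis")
  if (!all(need %in% names(e))) {
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  }
  if (!identical(names(object@colored), object@nodes) ||
      !identical(names(object@colors), object@nodes))
    msgs <- c(msgs, "colored/colors must be named by nodes")
  if (nrow(e)) {
    if (!all(c(e$gene_a, e$gene_b, e$color_gene) %in% object@nodes))
      msgs <- c(msgs, "edge genes missing from node set")
    if (any(e$gene_a > e$gene_b))
      msgs <- c(msgs, "edge endpoints must be sorted")
    if (any(e$weight < 1L)) msgs <- c(msgs, "edge weights must be positive")
    keys <- paste(e$gene_a, e$gene_b, e$color_gene, sep = "\r")
    if (anyDuplicated(keys)) msgs <- c(msgs, "duplicate edge keys")
    if (!identical(unname(lengths(object@provenance)[keys]),
                   as.integer(e$weight)))
      msgs <- c(msgs, "provenance sizes must equal edge weights")
  }
  if (length(msgs)) msgs else TRUE
})

#' SyntheticConfig: parameters of the synthetic eQTL cohort generator
#'
#' Fully determines a generated dataset given its `seed`. See
#' [generateDataset()] for the generative model.
#'
#' @slot nAffected,nUnaffected group sizes.
#' @slot nSnps,nGenes numbers of SNP loci and genes.
#' @slot mafRange range of the non-reference allele frequency.
#' @slot spikedPairs data.frame (`snp_a`, `snp_b`, `target_gene`, `effect`)
#'   of spiked two-locus interaction effects; SNP/gene entries may be
#'   1-based indices into the generated loci.
#' @slot spikedRelevant data.frame (`snp_id`, `shift`) of SNPs whose
#'   non-reference allele frequency is raised by `shift` in the affected
#'   group.
#' @slot noiseSd standard deviation of the Gaussian expression noise.
#' @slot seed integer RNG seed; the seed fully determines the output.
#' @seealso [syntheticConfig()]
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(nAffected = "integer", nUnaffected = "integer",
                 nSnps = "integer", nGenes = "integer",
                 mafRange = "numeric", spikedPairs = "data.frame",
                 spikedRelevant = "data.frame", noiseSd = "numeric",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  sizes <- c(object@nAffected, object@nUnaffected, object@nSnps, object@nGenes)
  if (any(sizes < 1L)) msgs <- c(msgs, "all sizes must be >= 1")
  mr <- object@mafRange
  if (length(mr) != 2L || mr[1L] > mr[2L] || mr[1L] < 0 || mr[2L] > 1)
    msgs <- c(msgs, "mafRange must be an increasing interval within [0,1]")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  sr <- object@spikedRelevant
  if (nrow(sr) && any(sr$shift < -1 | sr$shift > 1))
    msgs <- c(msgs, "relevance shifts must lie in [-1,1]")
  if (length(msgs)) msgs else TRUE
})
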