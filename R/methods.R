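# Accessors, show and subsetting methods for the core classes.

#' @describeIn GenotypeMatrix-class canonical call matrix (patients x SNPs).
#' @param x a `GenotypeMatrix`.
#' @aliases snpCalls
#' @export
setMethod("snpCalls", "GenotypeMatrix", function(x) x@calls)

#' @describeIn GenotypeMatrix-class per-SNP metadata `DataFrame`.
#' @aliases snpInfo
#' @export
setMethod("snpInfo", "GenotypeMatrix", function(x) x@snpInfo)

#' @describeIn GenotypeMatrix-class patient identifiers.
#' @aliases patientIds
#' @export
setMethod("patientIds", "GenotypeMatrix", function(x) rownames(x@calls))

#' @describeIn GenotypeMatrix-class SNP identifiers.
#' @aliases snpIds
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x) colnames(x@calls))

#' @describeIn GenotypeMatrix-class parse counters from reading.
#' @aliases parseReport
#' @export
setMethod("parseReport", "GenotypeMatrix", function(x) x@parseReport)

#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@calls))

#' @describeIn GenotypeMatrix-class subset patients (`i`) and/or SNPs (`j`).
#' @param i,j,drop patient and SNP indices; `drop` is ignored.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  calls <- x@calls
  if (!missing(i)) calls <- calls[i, , drop = FALSE]
  if (!missing(j)) calls <- calls[, j, drop = FALSE]
  info <- x@snpInfo[match(colnames(calls), x@snpInfo$snp_id), , drop = FALSE]
  new("GenotypeMatrix", calls = calls, snpInfo = info,
      parseReport = x@parseReport)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "patients x",
      ncol(object@calls), "SNPs\n")
  pr <- object@parseReport
  cat("  missing calls:", pr$nMissing %||% 0L,
      " unparseable:", pr$nUnparseable %||% 0L, "\n")
  invisible(object)
})

#' @describeIn SnpGeneMap-class SNP -> gene assignments (`NA` = unassigned).
#' @param x a `SnpGeneMap`.
#' @aliases geneAssignments
#' @export
setMethod("geneAssignments", "SnpGeneMap", function(x) x@assignments)

#' @describeIn SnpGeneMap-class SNP -> distance in bp (0 inside the locus).
#' @aliases snpDistances
#' @export
setMethod("snpDistances", "SnpGeneMap", function(x) x@distances)

#' @describeIn SnpGeneMap-class log of tie-broken assignments.
#' @aliases assignmentTies
#' @export
setMethod("assignmentTies", "SnpGeneMap", function(x) x@ties)

setMethod("show", "SnpGeneMap", function(object) {
  a <- object@assignments
  cat("SnpGeneMap:", length(a), "SNPs,", sum(!is.na(a)), "assigned to",
      length(unique(a[!is.na(a)])), "genes;", sum(is.na(a)), "unassigned\n")
  if (nrow(object@ties)) cat("  ties broken:", nrow(object@ties), "\n")
  invisible(object)
})

#' @describeIn AssocGraph-class edge table (`gene_a`, `gene_b`, `color_gene`,
#'   `weight`, `cis`).
#' @param x an `AssocGraph`.
#' @aliases edgeTable
#' @export
setMethod("edgeTable", "AssocGraph", function(x) x@edges)

#' @describeIn AssocGraph-class node table (`gene`, `colored`, `color`,
#'   `degree`).
#' @aliases nodeTable
#' @export
setMethod("nodeTable", "AssocGraph", function(x) {
  data.frame(gene = x@nodes, colored = unname(x@colored),
             color = unname(x@colors), degree = unname(nodeDegree(x)),
             stringsAsFactors = FALSE)
})

#' @describeIn AssocGraph-class edge key -> contributing canonical SNP pairs.
#' @aliases edgeProvenance
#' @export
setMethod("edgeProvenance", "AssocGraph", function(x) x@provenance)

#' @describeIn AssocGraph-class construction counters.
#' @aliases graphMeta
#' @export
setMethod("graphMeta", "AssocGraph", function(x) x@meta)

setMethod("show", "AssocGraph", function(object) {
  e <- object@edges
  cat("AssocGraph:", length(object@nodes), "genes (",
      sum(object@colored), "colored ),", nrow(e), "edges\n")
  if (nrow(e)) {
    cat("  total weight:", sum(e$weight),
        " max weight:", max(e$weight),
        " cis edges:", sum(e$cis), "\n")
  }
  m <- object@meta
  if (!is.null(m$tau)) cat("  weight filter tau =", m$tau, "\n")
  invisible(object)
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nAffected, "affected +",
      object@nUnaffected, "unaffected patients,", object@nSnps, "SNPs,",
      object@nGenes, "genes\n")
  cat("  maf ~ U(", object@mafRange[1L], ",", object@mafRange[2L],
      "), noise sd", object@noiseSd, ", seed", object@seed, "\n")
  cat("  spiked pairs:", nrow(object@spikedPairs),
      " spiked relevant SNPs:", nrow(object@spikedRelevant), "\n")
  invisible(object)
})
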