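#' Assign every SNP to its closest gene
#'
#' The mapping that drives association-graph construction: a SNP lying inside
#' a gene locus (start <= pos <= end, 1-based inclusive) is assigned to that
#' gene at distance 0; otherwise it is assigned to the same-chromosome gene
#' minimizing `min(|pos - start|, |pos - end|)`. SNPs with no same-chromosome
#' gene, no usable coordinates, or farther than `maxDist` from every gene are
#' left unassigned (`NA`), a valid outcome.
#'
#' Deterministic tie-breaking, independent of locus order: equal distance to
#' two genes goes to the gene with the smaller start coordinate; a SNP inside
#' two overlapping loci goes to the smaller-span locus (tie again by smaller
#' start). Broken ties are logged in the returned object.
#'
#' @param snps a [GenotypeMatrix-class], or a data.frame with columns
#'   `snp_id`, `chrom`, `pos`.
#' @param loci a `GRanges` from [readGeneLoci()], or a data.frame with
#'   columns `gene`, `chrom`, `start`, `end`.
#' @param maxDist optional maximum assignment distance in bp (default none).
#' @return a [SnpGeneMap-class].
#' @examples
#' snps <- data.frame(snp_id = c("s1", "s2"), chrom = "chr1",
#'                    pos = c(150L, 250L))
#' loci <- data.frame(gene = c("A", "B"), chrom = "chr1",
#'                    start = c(100L, 400L), end = c(200L, 500L))
#' geneAssignments(assignSnpsToGenes(snps, loci))
#' @export
assignSnpsToGenes <- function(snps, loci, maxDist = Inf) {
  if (is(snps, "GenotypeMatrix")) snps <- as.data.frame(snpInfo(snps))
  loci <- lociAsDataFrame(loci)
  if (nrow(loci) == 0L) stop("empty locus table")
  n <- nrow(snps)
  assignments <- rep(NA_character_, n)
  distances <- rep(NA_integer_, n)
  ties <- list()
  # order loci by the tie-break hierarchy once; within equal distance the
  # first candidate in this order wins
  span <- loci$end - loci$start + 1L
  lociOrd <- loci[order(loci$start, span), , drop = FALSE]
  spanOrd <- lociOrd$end - lociOrd$start + 1L
  for (i in seq_len(n)) {
    pos <- snps$pos[i]
    if (is.na(pos) || is.na(snps$chrom[i])) next
    cand <- which(lociOrd$chrom == snps$chrom[i])
    if (!length(cand)) next
    inside <- lociOrd$start[cand] <= pos & pos <= lociOrd$end[cand]
    d <- ifelse(inside, 0L,
                pmin(abs(pos - lociOrd$start[cand]),
                     abs(pos - lociOrd$end[cand])))
    if (any(inside)) {
      # containment dominance; overlapping loci resolved by smaller span
      inCand <- cand[inside]
      pick <- inCand[order(spanOrd[inCand], lociOrd$start[inCand])][1L]
      if (sum(inside) > 1L)
        ties[[length(ties) + 1L]] <-
          data.frame(snp_id = snps$snp_id[i], kind = "overlap",
                     chosen = lociOrd$gene[pick],
                     candidates = paste(lociOrd$gene[inCand], collapse = ","),
                     stringsAsFactors = FALSE)
      best <- pick; bestD <- 0L
    } else {
      dMin <- min(d)
      if (dMin > maxDist) next
      atMin <- cand[d == dMin]
      best <- atMin[order(lociOrd$start[atMin])][1L]
      bestD <- as.integer(dMin)
      if (length(atMin) > 1L)
        ties[[length(ties) + 1L]] <-
          data.frame(snp_id = snps$snp_id[i], kind = "distance",
                     chosen = lociOrd$gene[best],
                     candidates = paste(lociOrd$gene[atMin], collapse = ","),
                     stringsAsFactors = FALSE)
    }
    assignments[i] <- lociOrd$gene[best]
    distances[i] <- bestD
  }
  names(assignments) <- names(distances) <- snps$snp_id
  ties <- if (length(ties)) do.call(rbind, ties) else
    data.frame(snp_id = character(), kind = character(),
               chosen = character(), candidates = character(),
               stringsAsFactors = FALSE)
  new("SnpGeneMap", assignments = assignments, distances = distances,
      ties = ties)
}

# Accept GRanges or plain data.frame loci.
lociAsDataFrame <- function(loci) {
  if (is(loci, "GRanges")) {
    data.frame(gene = if (!is.null(names(loci))) names(loci) else
                 loci$gene,
               chrom = as.character(GenomicRanges::seqnames(loci)),
               start = GenomicRanges::start(loci),
               end = GenomicRanges::end(loci), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("gene", "chrom", "start", "end") %in% names(loci)))
    loci
  }
}
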