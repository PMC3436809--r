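# Writers for the same tab-separated formats the readers consume. Output is
# byte-stable: fixed number formatting, '\n' line endings, no locale
# dependence, so identical inputs give identical files.

#' Write a genotype table
#'
#' Inverse of [readGenotypeTable()]: first column patient id, one column per
#' SNP, missing calls written as `00`.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output file.
#' @export
writeGenotypeTable <- function(gm, path) {
  calls <- snpCalls(gm)
  body <- calls
  body[is.na(body)] <- "00"
  lines <- paste(rownames(calls),
                 apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  writeTsvLines(paste(c("patient", colnames(calls)), collapse = "\t"),
                lines, path)
}

#' Write a phenotype table
#' @param patients data.frame as from [readPhenotypeTable()].
#' @param path output file.
#' @param dialect dialect supplying column names and status coding.
#' @export
writePhenotypeTable <- function(patients, path, dialect = ioDialect()) {
  ph <- dialect$phenotype
  tok <- names(dialect$status_map)[match(as.character(patients$group),
                                         dialect$status_map)]
  writeTsvLines(paste(c(ph$family, ph$individual, ph$status), collapse = "\t"),
                paste(patients$family_id, patients$individual_id, tok,
                      sep = "\t"),
                path)
}

#' Write an expression table (genes in rows)
#' @param expr numeric matrix, genes x patients.
#' @param path output file.
#' @export
writeExpressionTable <- function(expr, path) {
  lines <- paste(rownames(expr),
                 apply(expr, 1L, function(v)
                   paste(formatNum(v), collapse = "\t")), sep = "\t")
  writeTsvLines(paste(c("gene", colnames(expr)), collapse = "\t"), lines, path)
}

#' Write the reference nucleotide table
#' @param refs named character vector, SNP id -> base.
#' @param path output file.
#' @export
writeReferenceTable <- function(refs, path) {
  writeTsvLines("SNP\tREF", paste(names(refs), refs, sep = "\t"), path)
}

#' Write gene loci (gene, chrom, start, end; 1-based inclusive)
#' @param loci a `GRanges` as from [readGeneLoci()].
#' @param path output file.
#' @export
writeGeneLoci <- function(loci, path) {
  writeTsvLines("gene\tchrom\tstart\tend",
                paste(names(loci),
                      as.character(GenomicRanges::seqnames(loci)),
                      GenomicRanges::start(loci), GenomicRanges::end(loci),
                      sep = "\t"),
                path)
}

#' Write single-locus results in the package's PLINK-like dialect
#' @param results data.frame as from [readSingleLocusResults()] or
#'   [singleLocusScan()].
#' @param path output file.
#' @param dialect dialect supplying column names.
#' @export
writeSingleLocusResults <- function(results, path, dialect = ioDialect()) {
  cols <- dialect$single
  writeTsvLines(paste(c(cols$snp, cols$trait, cols$p, cols$r2),
                      collapse = "\t"),
                paste(results$snp_id, results$trait_gene,
                      formatNum(results$p), formatNum(results$r2),
                      sep = "\t"),
                path)
}

#' Write two-locus results in the package's PLINK-like dialect
#' @param results data.frame as from [readPairResults()] or
#'   [twoLocusScan()].
#' @inheritParams writeSingleLocusResults
#' @export
writePairResults <- function(results, path, dialect = ioDialect()) {
  cols <- dialect$pair
  writeTsvLines(paste(c(cols$snp1, cols$snp2, cols$trait, cols$p),
                      collapse = "\t"),
                paste(results$snp_a, results$snp_b, results$trait_gene,
                      formatNum(results$p), sep = "\t"),
                path)
}
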