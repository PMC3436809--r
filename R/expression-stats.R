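# Differential-expression statistics for the heatmap views: per-gene
# two-sample t-tests, Benjamini-Hochberg FDR, ranks, and group mean profiles.

splitGroups <- function(expr, patients) {
  aff <- patients$patient_id[patients$group == "affected"]
  una <- patients$patient_id[patients$group == "unaffected"]
  miss <- setdiff(c(aff, una), colnames(expr))
  if (length(miss))
    stop("patients absent from expression matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  list(affected = expr[, aff, drop = FALSE],
       unaffected = expr[, una, drop = FALSE])
}

#' Two-sample t-test per gene
#'
#' Tests each gene's expression between the affected and unaffected groups
#' (two-sided; Welch by default, pooled-variance when `varEqual = TRUE`).
#' The t statistic is oriented affected minus unaffected. Degenerate genes
#' (zero variance in both groups and equal means) get t = 0, p = 1; with
#' different means, p = 0.
#'
#' @param expr numeric matrix, genes x patients.
#' @param patients phenotype data.frame.
#' @param varEqual pooled-variance t-test instead of Welch.
#' @return data.frame `gene`, `t`, `p`.
#' @export
ttestPerGene <- function(expr, patients, varEqual = FALSE) {
  gr <- splitGroups(expr, patients)
  if (ncol(gr$affected) < 2L || ncol(gr$unaffected) < 2L)
    stop("both groups need at least two patients")
  res <- t(vapply(rownames(expr), function(g) {
    a <- gr$affected[g, ]; u <- gr$unaffected[g, ]
    tt <- tryCatch(stats::t.test(a, u, var.equal = varEqual),
                   error = function(e) NULL)
    if (is.null(tt)) {   # essentially constant data
      if (isTRUE(all.equal(mean(a), mean(u)))) c(0, 1)
      else c(sign(mean(a) - mean(u)) * Inf, 0)
    } else {
      c(unname(tt$statistic), tt$p.value)
    }
  }, numeric(2L)))
  data.frame(gene = rownames(expr), t = res[, 1L], p = res[, 2L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values: `q_(i) = min_{j >= i} m p_(j) / j`, clipped at 1 and
#' mapped back to input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same order as the input.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Differential-expression gene ranking
#'
#' Combines [ttestPerGene()] with [bhFdr()] and ranks genes by p-value
#' (rank 1 = most significant).
#'
#' @inheritParams ttestPerGene
#' @return data.frame `gene`, `t`, `p`, `q`, `rank`.
#' @export
geneStats <- function(expr, patients, varEqual = FALSE) {
  out <- ttestPerGene(expr, patients, varEqual = varEqual)
  out$q <- bhFdr(out$p)
  out$rank <- as.integer(rank(out$p, ties.method = "first"))
  out
}

#' Group mean expression profiles
#'
#' Aggregates the cohort into one mean expression profile per disease group.
#'
#' @inheritParams ttestPerGene
#' @return numeric matrix, genes x 2 (`affected`, `unaffected`).
#' @export
groupMeanProfiles <- function(expr, patients) {
  gr <- splitGroups(expr, patients)
  if (ncol(gr$affected) == 0L || ncol(gr$unaffected) == 0L)
    stop("empty patient group")
  cbind(affected = rowMeans(gr$affected),
        unaffected = rowMeans(gr$unaffected))
}

#' Write the gene statistics table
#' @param stats data.frame from [geneStats()].
#' @param path output file.
#' @export
writeGeneStats <- function(stats, path) {
  writeTsvLines("gene\tt\tp\tq\trank",
                paste(stats$gene, formatNum(stats$t), formatNum(stats$p),
                      formatNum(stats$q), stats$rank, sep = "\t"),
                path)
}
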