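# Self-contained single- and two-locus association scans. These mirror the
# kind of quantitative-trait output a PLINK run would provide so the full
# pipeline can be exercised without external tools; they are a mirror of
# that convention, not a reimplementation of PLINK.

#' Additive genotype coding
#'
#' Codes each call as its number of non-reference alleles (0/1/2), `NA` for
#' missing calls.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param refs named reference-base vector covering the SNPs.
#' @return integer matrix, patients x SNPs.
#' @export
additiveCoding <- function(gm, refs) {
  calls <- snpCalls(gm)
  if (!all(colnames(calls) %in% names(refs)))
    stop("reference base missing for some SNPs")
  codes <- vapply(colnames(calls), function(s) {
    (substr(calls[, s], 1L, 1L) != refs[[s]]) +
      (substr(calls[, s], 2L, 2L) != refs[[s]])
  }, integer(nrow(calls)))
  rownames(codes) <- rownames(calls)
  codes
}

#' Single-locus association scan
#'
#' For every (SNP, gene) combination: simple linear regression of expression
#' on the additive genotype code, dropping patients with a missing call.
#' Reports the slope, its two-sided t-test p-value and the model r-squared.
#' Monomorphic SNPs (or fewer than three informative patients) are flagged
#' and get p = 1, r2 = 0.
#'
#' @param expr numeric matrix, genes x patients.
#' @param gm a [GenotypeMatrix-class] over the same patients.
#' @param refs named reference-base vector.
#' @return data.frame `snp_id`, `trait_gene`, `beta`, `t`, `p`, `r2`,
#'   `flag` (`""` or `"monomorphic"`).
#' @export
singleLocusScan <- function(expr, gm, refs) {
  ids <- colnames(expr)
  if (!all(ids %in% patientIds(gm)))
    stop("expression patients absent from genotype matrix")
  codes <- additiveCoding(gm, refs)[ids, , drop = FALSE]
  genes <- rownames(expr)
  out <- vector("list", ncol(codes))
  for (j in seq_len(ncol(codes))) {
    x <- codes[, j]
    valid <- !is.na(x)
    n <- sum(valid)
    mono <- n < 3L || stats::var(x[valid]) == 0
    if (mono) {
      out[[j]] <- data.frame(snp_id = colnames(codes)[j], trait_gene = genes,
                             beta = 0, t = 0, p = 1, r2 = 0,
                             flag = "monomorphic", stringsAsFactors = FALSE)
      next
    }
    xv <- x[valid]
    yv <- expr[, valid, drop = FALSE]
    r <- as.vector(stats::cor(xv, t(yv)))
    r2 <- r^2
    # exact fits leave no residual; p underflows to 0
    tstat <- r * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    sdy <- apply(yv, 1L, stats::sd)
    beta <- r * sdy / stats::sd(xv)
    out[[j]] <- data.frame(snp_id = colnames(codes)[j], trait_gene = genes,
                           beta = beta, t = tstat, p = p, r2 = r2,
                           flag = "", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-locus interaction scan
#'
#' For every requested SNP pair and every gene, fits the linear model
#' `expression ~ codeA + codeB + codeA:codeB` (additive coding) and reports
#' the two-sided t-test p-value of the interaction term — the two-locus
#' quantitative-trait convention. Pairs whose design matrix is rank
#' deficient (e.g. identical or collinear SNPs) are flagged `collinear` with
#' p = 1. Patients missing either call are dropped.
#'
#' @inheritParams singleLocusScan
#' @param pairs data.frame with columns `snp_a`, `snp_b`.
#' @return data.frame `snp_a`, `snp_b` (canonically sorted), `trait_gene`,
#'   `t`, `p`, `flag`.
#' @export
twoLocusScan <- function(expr, gm, refs, pairs) {
  ids <- colnames(expr)
  codes <- additiveCoding(gm, refs)[ids, , drop = FALSE]
  genes <- rownames(expr)
  sa <- pmin(pairs$snp_a, pairs$snp_b)
  sb <- pmax(pairs$snp_a, pairs$snp_b)
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- codes[, sa[k]]; b <- codes[, sb[k]]
    valid <- !is.na(a) & !is.na(b)
    n <- sum(valid)
    av <- a[valid]; bv <- b[valid]
    X <- cbind(1, av, bv, av * bv)
    qrX <- qr(X)
    if (n < 5L || qrX$rank < 4L) {
      out[[k]] <- data.frame(snp_a = sa[k], snp_b = sb[k],
                             trait_gene = genes, t = 0, p = 1,
                             flag = "collinear", stringsAsFactors = FALSE)
      next
    }
    Y <- t(expr[, valid, drop = FALSE])           # patients x genes
    coefs <- qr.coef(qrX, Y)
    res <- Y - X %*% coefs
    sigma2 <- colSums(res^2) / (n - 4L)
    xtxInv <- chol2inv(qr.R(qrX))
    se <- sqrt(sigma2 * xtxInv[4L, 4L])
    # a perfect fit (zero residual) is an infinitely significant interaction
    tstat <- ifelse(se > 0, coefs[4L, ] / se,
                    ifelse(abs(coefs[4L, ]) > 1e-12,
                           sign(coefs[4L, ]) * Inf, 0))
    p <- 2 * stats::pt(-abs(tstat), df = n - 4L)
    out[[k]] <- data.frame(snp_a = sa[k], snp_b = sb[k], trait_gene = genes,
                           t = unname(tstat), p = unname(p), flag = "",
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
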