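# Cohort genotype summarization: three-state simplification, per-group
# consensus + strength, the relevance rule, and per-SNP Pearson chi-squared
# tests of genotype independence between groups.

SIMPLE_STATES <- c("REF", "HET", "HOM")

#' Simplify genotype calls against the reference base
#'
#' Counts non-reference alleles: 0 -> `REF` (identical to the reference),
#' 1 -> `HET` (polymorphism in one allele), 2 -> `HOM` (polymorphism in both
#' alleles — also when the two non-reference alleles differ). Missing calls
#' stay `NA`.
#'
#' @param calls character vector of canonical calls (e.g. from
#'   [snpCalls()]), `NA` for missing.
#' @param ref single reference base, one of A/C/G/T.
#' @return factor with levels `REF`, `HET`, `HOM` (`NA` for missing calls).
#' @examples
#' simplifyGenotype(c("AA", "AC", "CG", NA), "A")
#' @export
simplifyGenotype <- function(calls, ref) {
  stopifnot(length(ref) == 1L, ref %in% BASES)
  nNonRef <- (substr(calls, 1L, 1L) != ref) + (substr(calls, 2L, 2L) != ref)
  factor(SIMPLE_STATES[nNonRef + 1L], levels = SIMPLE_STATES)
}

#' Summarize cohort genotypes per SNP and patient group
#'
#' Splits the cohort into the affected and unaffected groups and aggregates
#' each independently: the full genotype distribution, the simplified
#' three-state counts, the consensus (majority simplified state, ties broken
#' in the fixed order REF < HET < HOM) and its strength — the fraction of
#' non-missing patients carrying the consensus state. Missing calls are
#' excluded from all counts; a group with only missing calls gets an
#' undefined consensus (`NA`) and strength 0.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param patients phenotype data.frame (see [readPhenotypeTable()]);
#'   patients absent from the genotype matrix are an error.
#' @param snps SNP ids to summarize (default: all in `gm`).
#' @param refs named character vector of reference bases covering `snps`.
#' @return data.frame with one row per SNP x group: `snp_id`, `group`, `n`,
#'   `n_missing`, `n_ref`, `n_het`, `n_hom`, `consensus`, `strength`, and a
#'   list column `dist` of named genotype-count vectors.
#' @export
summarizeGenotypes <- function(gm, patients, snps = snpIds(gm), refs) {
  calls <- snpCalls(gm)
  miss <- setdiff(snps, colnames(calls))
  if (length(miss)) stop("SNP(s) absent from genotype matrix: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  if (!all(patients$patient_id %in% rownames(calls)))
    stop("phenotype table lists patients absent from the genotype matrix")
  if (!all(snps %in% names(refs)))
    stop("reference base missing for some SNPs")
  groups <- c("affected", "unaffected")
  rows <- vector("list", length(snps) * 2L)
  k <- 0L
  for (s in snps) {
    ref <- refs[[s]]
    for (grp in groups) {
      ids <- patients$patient_id[patients$group == grp]
      v <- calls[ids, s]
      nMissing <- sum(is.na(v))
      obs <- v[!is.na(v)]
      st <- simplifyGenotype(obs, ref)
      counts <- table(st)
      if (length(obs)) {
        best <- SIMPLE_STATES[which.max(counts[SIMPLE_STATES])]
        strength <- as.integer(max(counts)) / length(obs)
      } else {
        best <- NA_character_
        strength <- 0
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        snp_id = s, group = grp, n = length(ids), n_missing = nMissing,
        n_ref = as.integer(counts[["REF"]]),
        n_het = as.integer(counts[["HET"]]),
        n_hom = as.integer(counts[["HOM"]]),
        consensus = best, strength = strength, stringsAsFactors = FALSE)
      rows[[k]]$dist <- list(c(table(obs)))
    }
  }
  if (!length(rows)) {
    out <- data.frame(snp_id = character(), group = character(),
                      n = integer(), n_missing = integer(),
                      n_ref = integer(), n_het = integer(),
                      n_hom = integer(), consensus = character(),
                      strength = numeric(), stringsAsFactors = FALSE)
    out$dist <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect relevant SNPs from group summaries
#'
#' A SNP is flagged relevant when the affected and unaffected groups either
#' disagree in consensus state, or agree but differ in consensus strength by
#' at least `delta` (inclusive; default 10 percentage points, compared on
#' exact fractions with a 1e-12 tolerance). SNPs with an undefined consensus
#' in either group are excluded and reported in the `excluded` attribute.
#'
#' @param summaries data.frame from [summarizeGenotypes()] holding both
#'   groups for every SNP.
#' @param delta minimum strength difference (default 0.10).
#' @return character vector of relevant SNP ids, with attribute `excluded`.
#' @export
detectRelevantSnps <- function(summaries, delta = 0.10) {
  aff <- summaries[summaries$group == "affected", , drop = FALSE]
  una <- summaries[summaries$group == "unaffected", , drop = FALSE]
  una <- una[match(aff$snp_id, una$snp_id), , drop = FALSE]
  if (anyNA(una$snp_id)) stop("both groups must be summarized for every SNP")
  defined <- !is.na(aff$consensus) & !is.na(una$consensus)
  excluded <- aff$snp_id[!defined]
  stateDiff <- aff$consensus != una$consensus
  strengthDiff <- abs(aff$strength - una$strength) >= delta - 1e-12
  rel <- defined & (stateDiff | strengthDiff)
  out <- aff$snp_id[rel]
  attr(out, "excluded") <- excluded
  out
}

#' Pearson chi-squared test of genotype independence between groups
#'
#' Builds the 2 x c contingency table of the two groups' genotype
#' distributions (columns: the union of observed categories with a nonzero
#' total) and computes the Pearson statistic without continuity correction,
#' with df = c - 1 and the p-value from the chi-squared distribution. Tables
#' with fewer than two nonzero columns, or an empty group, are degenerate:
#' p = 1 by convention, flagged. Expected counts below 5 set the `caution`
#' flag but do not change the test.
#'
#' @param distAffected,distUnaffected named count vectors (genotype ->
#'   count), e.g. the `dist` column of [summarizeGenotypes()].
#' @return list with `statistic`, `df`, `p`, `degenerate`, `caution`.
#' @examples
#' chi2Independence(c(AA = 20, AC = 0), c(AA = 0, AC = 20))
#' @export
chi2Independence <- function(distAffected, distUnaffected) {
  cats <- sort(unique(c(names(distAffected), names(distUnaffected))))
  o <- rbind(affected = as.numeric(distAffected[cats]),
             unaffected = as.numeric(distUnaffected[cats]))
  o[is.na(o)] <- 0
  o <- o[, colSums(o) > 0, drop = FALSE]
  if (ncol(o) < 2L || any(rowSums(o) == 0)) {
    return(list(statistic = 0, df = 0L, p = 1, degenerate = TRUE,
                caution = FALSE))
  }
  expd <- outer(rowSums(o), colSums(o)) / sum(o)
  stat <- sum((o - expd)^2 / expd)
  df <- ncol(o) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       degenerate = FALSE, caution = any(expd < 5))
}

#' Per-SNP chi-squared tests across a SNP set
#'
#' Applies [chi2Independence()] to every SNP, with categories either the raw
#' genotype calls (default; allele combinations) or the simplified
#' three-state classes.
#'
#' @inheritParams summarizeGenotypes
#' @param categories `"genotype"` (raw allele pairs) or `"state"`
#'   (REF/HET/HOM; requires `refs`).
#' @return data.frame `snp_id`, `statistic`, `df`, `p`, `degenerate`,
#'   `caution`.
#' @export
chi2PerSnp <- function(gm, patients, snps = snpIds(gm),
                       categories = c("genotype", "state"), refs = NULL) {
  categories <- match.arg(categories)
  calls <- snpCalls(gm)
  if (categories == "state" && is.null(refs))
    stop("state categories require reference bases")
  affIds <- patients$patient_id[patients$group == "affected"]
  unaIds <- patients$patient_id[patients$group == "unaffected"]
  res <- lapply(snps, function(s) {
    va <- calls[affIds, s]; vu <- calls[unaIds, s]
    if (categories == "state") {
      va <- as.character(simplifyGenotype(va, refs[[s]]))
      vu <- as.character(simplifyGenotype(vu, refs[[s]]))
    }
    r <- chi2Independence(table(va[!is.na(va)]), table(vu[!is.na(vu)]))
    data.frame(snp_id = s, statistic = r$statistic, df = r$df, p = r$p,
               degenerate = r$degenerate, caution = r$caution,
               stringsAsFactors = FALSE)
  })
  if (!length(res)) {
    return(data.frame(snp_id = character(), statistic = numeric(),
                      df = integer(), p = numeric(), degenerate = logical(),
                      caution = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build the genotype-view model
#'
#' One column per selected SNP, the tabular backbone of the genotype view:
#' the -log10 p significance bar (the SNP's best single-locus p over all
#' traits, clamped at `pFloor`; the minimizing trait is recorded), both group
#' summaries, the chi-squared p, the relevance flag, the reference base and
#' the focus patient's call. Columns are ordered by genomic position
#' (chrom, pos) by default, or by the cohort-majority genotype.
#'
#' @param selection SNP ids to display.
#' @param gm a [GenotypeMatrix-class].
#' @param patients phenotype data.frame.
#' @param refs named reference-base vector.
#' @param singleResults single-locus results (for the significance bar); may
#'   be `NULL`, leaving the bar empty (`NA`).
#' @param focusPatient patient id shown in the individual row (default:
#'   first patient).
#' @param orderBy `"position"` or `"majority"`.
#' @param delta relevance threshold passed to [detectRelevantSnps()].
#' @param pFloor clamp for p = 0 before the log transform (default 1e-300,
#'   i.e. a bar height capped at 300).
#' @return data.frame with one row per SNP column, including list columns
#'   `dist_affected` / `dist_unaffected` with the raw genotype counts.
#' @export
buildGenotypeViewModel <- function(selection, gm, patients, refs,
                                   singleResults = NULL,
                                   focusPatient = patients$patient_id[1L],
                                   orderBy = c("position", "majority"),
                                   delta = 0.10, pFloor = 1e-300) {
  orderBy <- match.arg(orderBy)
  stopifnot(focusPatient %in% patients$patient_id)
  if (!length(selection)) {
    out <- data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), neg_log_p = numeric(),
                      best_trait = character(), ref_allele = character(),
                      individual_call = character(),
                      consensus_affected = character(),
                      strength_affected = numeric(),
                      n_missing_affected = integer(),
                      consensus_unaffected = character(),
                      strength_unaffected = numeric(),
                      n_missing_unaffected = integer(),
                      relevant = logical(), chi2_p = numeric(),
                      stringsAsFactors = FALSE)
    out$dist_affected <- list()
    out$dist_unaffected <- list()
    return(out)
  }
  summ <- summarizeGenotypes(gm, patients, selection, refs)
  relevant <- detectRelevantSnps(summ, delta = delta)
  chi2 <- chi2PerSnp(gm, patients, selection)
  info <- as.data.frame(snpInfo(gm))
  info <- info[match(selection, info$snp_id), , drop = FALSE]
  aff <- summ[summ$group == "affected", , drop = FALSE]
  una <- summ[summ$group == "unaffected", , drop = FALSE]
  aff <- aff[match(selection, aff$snp_id), , drop = FALSE]
  una <- una[match(selection, una$snp_id), , drop = FALSE]
  if (!is.null(singleResults)) {
    sub <- singleResults[singleResults$snp_id %in% selection, , drop = FALSE]
    bestIdx <- tapply(seq_len(nrow(sub)), sub$snp_id,
                      function(i) i[which.min(sub$p[i])])
    bestP <- stats::setNames(sub$p[unlist(bestIdx)], names(bestIdx))
    bestTrait <- stats::setNames(sub$trait_gene[unlist(bestIdx)],
                                 names(bestIdx))
  } else {
    bestP <- bestTrait <- NULL
  }
  p <- if (is.null(bestP)) rep(NA_real_, length(selection))
       else unname(bestP[selection])
  trait <- if (is.null(bestTrait)) rep(NA_character_, length(selection))
           else unname(bestTrait[selection])
  out <- data.frame(
    snp_id = selection,
    chrom = info$chrom, pos = info$pos,
    neg_log_p = ifelse(is.na(p), NA_real_, -log10(pmax(p, pFloor))),
    best_trait = trait,
    ref_allele = unname(refs[selection]),
    individual_call = unname(snpCalls(gm)[focusPatient, selection]),
    consensus_affected = aff$consensus, strength_affected = aff$strength,
    n_missing_affected = aff$n_missing,
    consensus_unaffected = una$consensus, strength_unaffected = una$strength,
    n_missing_unaffected = una$n_missing,
    relevant = selection %in% relevant,
    chi2_p = chi2$p[match(selection, chi2$snp_id)],
    stringsAsFactors = FALSE)
  out$dist_affected <- aff$dist
  out$dist_unaffected <- una$dist
  ord <- if (orderBy == "position") {
    order(out$chrom, out$pos, out$snp_id)
  } else {
    # majority genotype of the pooled cohort, then descending pooled strength
    pooledState <- mapply(function(a, u) {
      counts <- c(n_ref = a[["n_ref"]] + u[["n_ref"]],
                  n_het = a[["n_het"]] + u[["n_het"]],
                  n_hom = a[["n_hom"]] + u[["n_hom"]])
      which.max(counts)
    }, split(aff[, c("n_ref", "n_het", "n_hom")], seq_len(nrow(aff))),
       split(una[, c("n_ref", "n_het", "n_hom")], seq_len(nrow(una))))
    pooledStrength <- (aff$strength * (aff$n - aff$n_missing) +
                       una$strength * (una$n - una$n_missing))
    order(pooledState, -pooledStrength, out$snp_id)
  }
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the genotype-view table
#'
#' Companion tab-separated table of [buildGenotypeViewModel()] output, one
#' row per SNP column (distribution list columns serialized as
#' `genotype:count` pairs).
#'
#' @param view data.frame from [buildGenotypeViewModel()].
#' @param path output file.
#' @export
writeGenotypeViewTable <- function(view, path) {
  fmtDist <- function(d) vapply(d, function(x) {
    if (!length(x)) return("")
    paste(paste0(names(x), ":", as.integer(x)), collapse = ",")
  }, "")
  flat <- view[, setdiff(names(view), c("dist_affected", "dist_unaffected"))]
  flat$dist_affected <- fmtDist(view$dist_affected)
  flat$dist_unaffected <- fmtDist(view$dist_unaffected)
  num <- vapply(flat, is.numeric, NA)
  body <- flat
  for (j in which(num)) body[[j]] <- ifelse(is.na(flat[[j]]), "NA",
                                            sprintf("%.10g", flat[[j]]))
  writeTsvLines(paste(names(body), collapse = "\t"),
                do.call(paste, c(unname(as.list(body)), sep = "\t")), path)
}
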