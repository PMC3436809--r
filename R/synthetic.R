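# Seeded synthetic eQTL cohort generator with known ground truth: all six
# input tables plus a manifest of spiked effects, for tests and demos.

#' Construct a synthetic cohort configuration
#'
#' Defaults emulate the shape of a mid-sized case/control eQTL cohort: 193
#' affected and 307 unaffected patients, 200 biallelic SNP loci tiled across
#' the loci of 10 genes on one synthetic chromosome, non-reference allele
#' frequencies uniform on `mafRange`, Hardy-Weinberg genotypes with
#' independent SNPs (no linkage disequilibrium), and unit-variance Gaussian
#' expression noise.
#'
#' Two kinds of ground-truth signal can be spiked in:
#'
#' * `spikedPairs`: a two-locus interaction — the target gene's expression
#'   gains `effect * codeA * codeB` (additive codings of the two SNPs).
#'   These SNPs draw their allele frequency from U(0.35, 0.5): interaction
#'   effects on common variants also induce the marginal single-locus signal
#'   that the filter cascade conditions on, which is the regime the recovery
#'   checks probe (see the methods vignette for the power analysis).
#' * `spikedRelevant`: a group-differential genotype — the affected group's
#'   non-reference allele frequency is raised by `shift`. The baseline
#'   frequency is drawn from U(low, 0.45 - shift) so the programmed shift
#'   expresses as a consensus-state or consensus-strength difference rather
#'   than cancelling inside the heterozygote-majority band.
#'
#' SNP/gene identifiers in the spike tables may be given as 1-based indices
#' (resolved against the generated loci) or as final ids/names.
#'
#' @param nAffected,nUnaffected group sizes.
#' @param nSnps,nGenes numbers of SNPs and genes.
#' @param mafRange interval for the non-reference allele frequency.
#' @param spikedPairs data.frame (`snp_a`, `snp_b`, `target_gene`,
#'   `effect`); zero-row default.
#' @param spikedRelevant data.frame (`snp_id`, `shift`); zero-row default.
#' @param noiseSd expression noise standard deviation.
#' @param seed integer seed; fully determines the generated dataset.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nAffected = 193L, nUnaffected = 307L,
                            nSnps = 200L, nGenes = 10L,
                            mafRange = c(0.05, 0.5),
                            spikedPairs = NULL, spikedRelevant = NULL,
                            noiseSd = 1.0, seed = 1L) {
  if (is.null(spikedPairs))
    spikedPairs <- data.frame(snp_a = integer(), snp_b = integer(),
                              target_gene = integer(), effect = numeric())
  if (is.null(spikedRelevant))
    spikedRelevant <- data.frame(snp_id = integer(), shift = numeric())
  new("SyntheticConfig", nAffected = as.integer(nAffected),
      nUnaffected = as.integer(nUnaffected), nSnps = as.integer(nSnps),
      nGenes = as.integer(nGenes), mafRange = as.numeric(mafRange),
      spikedPairs = spikedPairs, spikedRelevant = spikedRelevant,
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

resolveIdx <- function(x, ids) {
  if (is.numeric(x)) ids[as.integer(x)] else as.character(x)
}

#' Generate a synthetic eQTL dataset
#'
#' Draws a complete, self-consistent cohort under `config` and (optionally)
#' writes the six input tables plus a ground-truth manifest to `dir`. Gene
#' loci tile one synthetic chromosome (`chr1`), each gene owning an equal
#' share of the SNPs, placed inside its locus; SNP ids are `chr1:pos`.
#' Genotypes are Hardy-Weinberg draws of the per-SNP non-reference allele
#' count, with the affected group's frequency shifted for spiked-relevant
#' SNPs. Expression is zero-baseline plus the spiked interaction effects
#' plus Gaussian noise. The reference allele is the major allele of the
#' combined cohort (ties broken alphabetically), so a spiked frequency above
#' 0.5 can legitimately flip the reference.
#'
#' The same seed always yields byte-identical files.
#'
#' @param config a [SyntheticConfig-class].
#' @param dir output directory (created); `NULL` for in-memory only.
#' @return (invisibly when writing) a list with `genotypes`
#'   ([GenotypeMatrix-class]), `expression` (genes x patients), `patients`,
#'   `refs`, `loci` (`GRanges`), `manifest` (spiked truth table), `config`,
#'   and `paths` when written.
#' @export
generateDataset <- function(config, dir = NULL) {
  stopifnot(is(config, "SyntheticConfig"))
  set.seed(config@seed)
  nP <- config@nAffected + config@nUnaffected
  nS <- config@nSnps; nG <- config@nGenes
  patientId <- sprintf("P%04d", seq_len(nP))
  patients <- data.frame(
    family_id = sprintf("F%04d", seq_len(nP)),
    individual_id = patientId, patient_id = patientId,
    group = factor(rep(c("affected", "unaffected"),
                       c(config@nAffected, config@nUnaffected)),
                   levels = c("affected", "unaffected")),
    stringsAsFactors = FALSE)

  # loci tile chr1: gene g owns [ (g-1)*1e5+1, (g-1)*1e5+6e4 ]
  geneNames <- sprintf("G%02d", seq_len(nG))
  lociStart <- (seq_len(nG) - 1L) * 100000L + 1L
  lociEnd <- lociStart + 60000L - 1L
  loci <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(start = lociStart, end = lociEnd),
            gene = geneNames)
  names(loci) <- geneNames

  # SNPs spread evenly over genes, placed inside each locus
  snpGene <- sort(rep(seq_len(nG), length.out = nS))
  offset <- unlist(lapply(table(snpGene), function(k)
    round(seq(1000, 59000, length.out = k))))
  pos <- lociStart[snpGene] + as.integer(offset)
  snpIdsV <- paste0("chr1:", pos)

  spikedPairs <- config@spikedPairs
  spikedRelevant <- config@spikedRelevant
  pairSnps <- unique(c(resolveIdx(spikedPairs$snp_a, snpIdsV),
                       resolveIdx(spikedPairs$snp_b, snpIdsV)))
  relSnps <- resolveIdx(spikedRelevant$snp_id, snpIdsV)
  relShift <- stats::setNames(spikedRelevant$shift, relSnps)
  if (length(intersect(pairSnps, relSnps)))
    stop("a SNP cannot carry both an interaction and a relevance spike")

  # allele frequencies: see syntheticConfig() for the spiked-SNP ranges
  maf <- stats::runif(nS, config@mafRange[1L], config@mafRange[2L])
  names(maf) <- snpIdsV
  maf[pairSnps] <- stats::runif(length(pairSnps), 0.35, 0.5)
  if (length(relSnps)) {
    hi <- pmin(config@mafRange[2L], 0.45 - abs(relShift))
    if (any(hi <= config@mafRange[1L]))
      stop("relevance shift too large for mafRange")
    maf[relSnps] <- config@mafRange[1L] +
      stats::runif(length(relSnps)) * (hi - config@mafRange[1L])
  }
  mafAff <- maf
  mafAff[relSnps] <- maf[relSnps] + relShift
  if (any(mafAff < 0 | mafAff > 1))
    stop("shift pushes allele frequency outside [0, 1]")

  # two alleles per SNP; genotype = Hardy-Weinberg draw of alt count
  refCand <- sample(BASES, nS, replace = TRUE)
  altCand <- vapply(refCand, function(b) sample(setdiff(BASES, b), 1L), "")
  isAff <- patients$group == "affected"
  freqs <- matrix(rep(maf, each = nP), nrow = nP)
  freqs[isAff, ] <- rep(mafAff, each = sum(isAff))
  altCount <- matrix(stats::rbinom(nP * nS, 2L, as.vector(freqs)),
                     nrow = nP, dimnames = list(patientId, snpIdsV))

  callStrings <- function(j) {
    g <- altCount[, j]
    a1 <- ifelse(g >= 1L, altCand[j], refCand[j])
    a2 <- ifelse(g == 2L, altCand[j], refCand[j])
    paste0(pmin(a1, a2), pmax(a1, a2))
  }
  calls <- vapply(seq_len(nS), callStrings, character(nP))
  dimnames(calls) <- list(patientId, snpIdsV)

  # reference allele: major allele of the combined cohort, ties alphabetical
  refs <- vapply(seq_len(nS), function(j) {
    alleles <- c(rep(refCand[j], sum(2L - altCount[, j])),
                 rep(altCand[j], sum(altCount[, j])))
    tab <- sort(table(factor(alleles, levels = BASES)), decreasing = TRUE)
    cands <- names(tab)[tab == max(tab)]
    sort(cands)[1L]
  }, "")
  names(refs) <- snpIdsV

  expr <- matrix(stats::rnorm(nG * nP, sd = config@noiseSd), nrow = nG,
                 dimnames = list(geneNames, patientId))
  manifest <- data.frame(kind = character(), snp_a = character(),
                         snp_b = character(), target_gene = character(),
                         value = numeric(), stringsAsFactors = FALSE)
  if (nrow(spikedPairs)) {
    sa <- resolveIdx(spikedPairs$snp_a, snpIdsV)
    sb <- resolveIdx(spikedPairs$snp_b, snpIdsV)
    tg <- resolveIdx(spikedPairs$target_gene, geneNames)
    for (k in seq_len(nrow(spikedPairs))) {
      codeA <- nonRefCount(calls[, sa[k]], refs[[sa[k]]])
      codeB <- nonRefCount(calls[, sb[k]], refs[[sb[k]]])
      expr[tg[k], ] <- expr[tg[k], ] +
        spikedPairs$effect[k] * codeA * codeB
    }
    manifest <- rbind(manifest, data.frame(
      kind = "interaction", snp_a = pmin(sa, sb), snp_b = pmax(sa, sb),
      target_gene = tg, value = spikedPairs$effect,
      stringsAsFactors = FALSE))
  }
  if (length(relSnps)) {
    manifest <- rbind(manifest, data.frame(
      kind = "relevant", snp_a = relSnps, snp_b = NA_character_,
      target_gene = NA_character_, value = unname(relShift),
      stringsAsFactors = FALSE))
  }

  gm <- new("GenotypeMatrix", calls = calls,
            snpInfo = S4Vectors::DataFrame(parseSnpPositions(snpIdsV)),
            parseReport = list(nMissing = 0L, nUnparseable = 0L))
  out <- list(genotypes = gm, expression = expr, patients = patients,
              refs = refs, loci = loci, manifest = manifest, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(genotypes = file.path(dir, "genotypes.tsv"),
                  expression = file.path(dir, "expression.tsv"),
                  phenotypes = file.path(dir, "phenotypes.tsv"),
                  reference = file.path(dir, "reference.tsv"),
                  loci = file.path(dir, "gene_loci.tsv"),
                  manifest = file.path(dir, "manifest.tsv"))
    writeGenotypeTable(gm, paths$genotypes)
    writeExpressionTable(expr, paths$expression)
    writePhenotypeTable(patients, paths$phenotypes)
    writeReferenceTable(refs, paths$reference)
    writeGeneLoci(loci, paths$loci)
    writeTsvLines("kind\tsnp_a\tsnp_b\ttarget_gene\tvalue",
                  paste(manifest$kind, manifest$snp_a, manifest$snp_b,
                        manifest$target_gene, formatNum(manifest$value),
                        sep = "\t"),
                  paths$manifest)
    out$paths <- paths
  }
  out
}

nonRefCount <- function(calls, ref) {
  (substr(calls, 1L, 1L) != ref) + (substr(calls, 2L, 2L) != ref)
}

#' Generate PLINK-style result files for a synthetic dataset
#'
#' Runs [singleLocusScan()] over every (SNP, gene) combination and
#' [twoLocusScan()] over the requested SNP pairs (default: all spiked pairs
#' plus `nRandomPairs` random distinct pairs), optionally writing both in
#' the dialect the readers consume.
#'
#' @param dataset list from [generateDataset()].
#' @param pairs data.frame (`snp_a`, `snp_b`) of pairs to scan; `NULL` for
#'   the default described above.
#' @param nRandomPairs number of random pairs when `pairs` is `NULL`.
#' @param dir output directory; `NULL` for in-memory only.
#' @return list with `single` and `pair` result data.frames (and `paths`
#'   when written).
#' @export
generateResultFiles <- function(dataset, pairs = NULL, nRandomPairs = 300L,
                                dir = NULL) {
  gm <- dataset$genotypes
  ids <- snpIds(gm)
  if (is.null(pairs)) {
    man <- dataset$manifest
    spiked <- man[man$kind == "interaction", c("snp_a", "snp_b"),
                  drop = FALSE]
    # distinct random pairs, deterministic continuation of the dataset seed
    i <- sample.int(length(ids), nRandomPairs, replace = TRUE)
    j <- sample.int(length(ids) - 1L, nRandomPairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    rnd <- data.frame(snp_a = pmin(ids[i], ids[j]),
                      snp_b = pmax(ids[i], ids[j]),
                      stringsAsFactors = FALSE)
    pairs <- rbind(spiked, rnd)
    pairs <- pairs[!duplicated(paste(pairs$snp_a, pairs$snp_b)), ,
                   drop = FALSE]
  }
  single <- singleLocusScan(dataset$expression, gm, dataset$refs)
  pair <- twoLocusScan(dataset$expression, gm, dataset$refs, pairs)
  out <- list(single = single, pair = pair)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(single = file.path(dir, "single_locus.tsv"),
                  pair = file.path(dir, "two_locus.tsv"))
    writeSingleLocusResults(single, paths$single)
    writePairResults(pair, paths$pair)
    out$paths <- paths
  }
  out
}
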