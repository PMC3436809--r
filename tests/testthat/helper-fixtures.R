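# Fixture builders shared across the test files. All fixtures are generated
# in code; nothing is stored on disk.

writeTempTsv <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# GenotypeMatrix from an additive-code matrix (patients x SNPs, 0/1/2 or NA)
gmFromCodes <- function(codes, ref = "A", alt = "C") {
  stopifnot(!is.null(dimnames(codes)))
  geno <- c(paste0(ref, ref),
            paste0(pmin(ref, alt), pmax(ref, alt)),
            paste0(alt, alt))
  calls <- matrix(geno[codes + 1L], nrow = nrow(codes),
                  dimnames = dimnames(codes))
  new("GenotypeMatrix", calls = calls,
      snpInfo = S4Vectors::DataFrame(
        eqtlnet:::parseSnpPositions(colnames(codes))),
      parseReport = list(nMissing = sum(is.na(codes)), nUnparseable = 0L))
}

makePatients <- function(nAffected, nUnaffected) {
  n <- nAffected + nUnaffected
  id <- sprintf("P%03d", seq_len(n))
  data.frame(family_id = id, individual_id = id, patient_id = id,
             group = factor(rep(c("affected", "unaffected"),
                                c(nAffected, nUnaffected)),
                            levels = c("affected", "unaffected")),
             stringsAsFactors = FALSE)
}

# Independent brute-force oracle for association-graph edge weights: a plain
# dictionary count over gene triples, one contribution per distinct
# canonical SNP pair.
bruteForceEdgeWeights <- function(pairs, assignments, alpha = 0.05) {
  seenPair <- character()
  counts <- list()
  for (i in seq_len(nrow(pairs))) {
    if (!(pairs$p[i] < alpha)) next
    ga <- assignments[[pairs$snp_a[i]]]
    gb <- assignments[[pairs$snp_b[i]]]
    if (is.na(ga) || is.na(gb)) next
    pid <- paste(sort(c(pairs$snp_a[i], pairs$snp_b[i])), collapse = "|")
    key <- paste(sort(c(ga, gb))[1], sort(c(ga, gb))[2],
                 pairs$trait_gene[i], sep = "\r")
    pk <- paste(pid, pairs$trait_gene[i])
    if (pk %in% seenPair) next
    seenPair <- c(seenPair, pk)
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small fully-wired random analysis instance (loci, map, pairs).
randomGraphInstance <- function(nGenes, nSnps, nPairs) {
  genes <- sprintf("G%02d", seq_len(nGenes))
  loci <- data.frame(gene = genes, chrom = "chr1",
                     start = (seq_len(nGenes) - 1L) * 1000L + 1L,
                     end = (seq_len(nGenes) - 1L) * 1000L + 800L)
  snps <- sprintf("s%03d", seq_len(nSnps))
  asn <- sample(c(genes, NA_character_), nSnps, replace = TRUE,
                prob = c(rep(1, nGenes), 0.15 * nGenes))
  names(asn) <- snps
  map <- new("SnpGeneMap", assignments = asn,
             distances = stats::setNames(
               ifelse(is.na(asn), NA_integer_, 0L), snps),
             ties = data.frame(snp_id = character(), kind = character(),
                               chosen = character(),
                               candidates = character()))
  i <- sample.int(nSnps, nPairs, replace = TRUE)
  j <- sample.int(nSnps - 1L, nPairs, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)
  pairs <- data.frame(snp_a = pmin(snps[i], snps[j]),
                      snp_b = pmax(snps[i], snps[j]),
                      trait_gene = sample(genes, nPairs, replace = TRUE),
                      p = stats::runif(nPairs),
                      stringsAsFactors = FALSE)
  list(loci = loci, map = map, pairs = pairs, genes = genes)
}
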