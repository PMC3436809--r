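# Readers for the six tab-separated input tables. All parsing is
# header-keyed, tab-separated, with '#'-prefixed comment lines ignored.

#' Read a per-patient genotype table
#'
#' The first column holds the patient id; every further column is one SNP,
#' its header the SNP id. Cells are genotype tokens canonicalized by
#' [parseCalls()]; tokens in the dialect's missing set and unparseable cells
#' become missing calls and are counted in the parse report. SNP coordinates
#' are derived from `"chr:pos"`-style SNP ids where possible.
#'
#' @param path file path.
#' @param dialect a dialect from [ioDialect()].
#' @return a [GenotypeMatrix-class] object.
#' @export
readGenotypeTable <- function(path, dialect = ioDialect()) {
  df <- readTsvChar(path)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty genotype table: ", path)
  patients <- df[[1L]]
  if (anyDuplicated(patients))
    stop("duplicate patient id(s): ",
         paste(unique(patients[duplicated(patients)]), collapse = ", "))
  snps <- names(df)[-1L]
  if (anyDuplicated(snps))
    stop("duplicate SNP column(s): ",
         paste(unique(snps[duplicated(snps)]), collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  parsed <- parseCalls(raw, missingTokens = dialect$missing_tokens)
  calls <- matrix(as.character(parsed), nrow = nrow(raw),
                  dimnames = list(patients, snps))
  info <- S4Vectors::DataFrame(parseSnpPositions(snps))
  new("GenotypeMatrix", calls = calls, snpInfo = info,
      parseReport = list(nMissing = attr(parsed, "nMissing"),
                         nUnparseable = attr(parsed, "nUnparseable")))
}

#' Read the patient phenotype table
#'
#' Expects columns for family id, individual id and affection status (names
#' per dialect). Status tokens are mapped via the dialect's `status_map`
#' (PLINK convention: 2 = affected, 1 = unaffected).
#'
#' @inheritParams readGenotypeTable
#' @return data.frame with columns `family_id`, `individual_id`,
#'   `patient_id` (the individual id) and `group` (factor
#'   affected/unaffected).
#' @export
readPhenotypeTable <- function(path, dialect = ioDialect()) {
  df <- readTsvChar(path)
  ph <- dialect$phenotype
  assertColumns(df, ph, path)
  status <- trimws(df[[ph$status]])
  group <- unname(dialect$status_map[status])
  bad <- which(is.na(group))
  if (length(bad))
    stop("unknown affection status token '", status[bad[1L]],
         "' in row ", bad[1L], " of ", path)
  key <- paste(df[[ph$family]], df[[ph$individual]], sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate (family, individual) pair in row ", d, ": ",
         df[[ph$family]][d], "/", df[[ph$individual]][d])
  }
  data.frame(family_id = df[[ph$family]],
             individual_id = df[[ph$individual]],
             patient_id = df[[ph$individual]],
             group = factor(group, levels = c("affected", "unaffected")),
             stringsAsFactors = FALSE)
}

#' Read a gene expression table
#'
#' By default genes are in rows (first column gene names, further columns one
#' per patient). Set `patientsInRows = TRUE` for the transposed layout; the
#' returned matrix is always genes x patients. Non-numeric body cells and
#' ragged rows are errors.
#'
#' @param path file path.
#' @param patientsInRows is the file transposed (patients in rows)?
#' @return numeric matrix, genes in rows, patients in columns.
#' @export
readExpressionTable <- function(path, patientsInRows = FALSE) {
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#", quote = "")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L)
    stop("ragged rows in ", path, ": field counts ",
         paste(unique(nf), collapse = ", "))
  df <- readTsvChar(path)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty expression table: ", path)
  rn <- df[[1L]]
  if (anyDuplicated(rn)) stop("duplicate row names in ", path)
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !(toupper(trimws(body)) %in% c("NA")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric expression value '", body[bad[1L, 1L], bad[1L, 2L]],
         "' at row ", rn[bad[1L, 1L]], ", column ",
         colnames(body)[bad[1L, 2L]])
  }
  dimnames(num) <- list(rn, colnames(body))
  if (patientsInRows) num <- t(num)
  num
}

#' Read the per-SNP reference nucleotide table
#'
#' Two columns: SNP id and reference base. A header line is detected and
#' skipped when its second field is not a nucleotide. Bases are uppercased;
#' anything outside A/C/G/T is an error, as are conflicting duplicate
#' entries (consistent duplicates collapse).
#'
#' @param path file path.
#' @return named character vector, SNP id -> reference base.
#' @export
readReferenceTable <- function(path) {
  df <- readTsvChar(path, header = FALSE)
  if (ncol(df) < 2L) stop("reference table needs two columns: ", path)
  headerLike <- nrow(df) && !(toupper(trimws(df[1L, 2L])) %in% BASES) &&
    grepl("REF|BASE|ALLELE|NUC", toupper(df[1L, 2L]))
  if (headerLike) df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty reference table: ", path)
  ids <- trimws(df[[1L]])
  base <- toupper(trimws(df[[2L]]))
  bad <- which(!(base %in% BASES))
  if (length(bad))
    stop("invalid reference base '", base[bad[1L]], "' for SNP ", ids[bad[1L]])
  refs <- stats::setNames(base, ids)
  if (anyDuplicated(ids)) {
    split_ <- split(base, ids)
    conflict <- names(split_)[vapply(split_, function(b)
      length(unique(b)) > 1L, NA)]
    if (length(conflict))
      stop("conflicting reference bases for SNP(s): ",
           paste(conflict, collapse = ", "))
    refs <- refs[!duplicated(ids)]
  }
  refs
}

#' Read gene loci
#'
#' Default format: four tab-separated columns gene, chrom, start, end with
#' 1-based inclusive coordinates (header optional). With `bed = TRUE` the
#' file is BED-like (chrom, start, end, name; 0-based half-open) and is
#' converted.
#'
#' @param path file path.
#' @param bed interpret as BED (0-based half-open) instead.
#' @return a [GenomicRanges::GRanges] named by gene, with a `gene` metadata
#'   column.
#' @export
readGeneLoci <- function(path, bed = FALSE) {
  df <- readTsvChar(path, header = FALSE)
  if (ncol(df) < 4L) stop("gene locus table needs four columns: ", path)
  numCols <- if (bed) c(2L, 3L) else c(3L, 4L)
  if (nrow(df) &&
      anyNA(suppressWarnings(as.numeric(unlist(df[1L, numCols])))))
    df <- df[-1L, , drop = FALSE]   # header line
  if (nrow(df) == 0L) stop("empty gene locus table: ", path)
  if (bed) {
    gene <- trimws(df[[4L]]); chrom <- trimws(df[[1L]])
    start <- as.numeric(df[[2L]]) + 1; end <- as.numeric(df[[3L]])
  } else {
    gene <- trimws(df[[1L]]); chrom <- trimws(df[[2L]])
    start <- as.numeric(df[[3L]]); end <- as.numeric(df[[4L]])
  }
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinates in ", path)
  if (any(start > end)) stop("locus with start > end in ", path)
  if (anyDuplicated(gene))
    stop("duplicate gene name(s): ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = start, end = end), gene = gene)
  names(gr) <- gene
  gr
}

#' Read single-locus association results
#'
#' Header-keyed per the dialect (`SNP`, `TRAIT`, `P`, `R2` by default,
#' mirroring PLINK quantitative-trait output plus an explicit trait column).
#' Rows with unparseable or out-of-bounds `P`/`R2` are dropped with one
#' warning carrying the count (also attached as attribute `nDropped`).
#' Duplicate (SNP, trait) records are an error.
#'
#' @inheritParams readGenotypeTable
#' @return data.frame with columns `snp_id`, `trait_gene`, `p`, `r2`.
#' @export
readSingleLocusResults <- function(path, dialect = ioDialect()) {
  df <- readTsvChar(path)
  cols <- dialect$single
  assertColumns(df, cols, path)
  p <- suppressWarnings(as.numeric(df[[cols$p]]))
  r2 <- suppressWarnings(as.numeric(df[[cols$r2]]))
  keep <- !is.na(p) & !is.na(r2) & p >= 0 & p <= 1 & r2 >= 0 & r2 <= 1
  nDropped <- sum(!keep)
  if (nDropped)
    warning(nDropped, " row(s) with unparseable or out-of-bounds P/R2 ",
            "dropped from ", path)
  out <- data.frame(snp_id = trimws(df[[cols$snp]])[keep],
                    trait_gene = trimws(df[[cols$trait]])[keep],
                    p = p[keep], r2 = r2[keep], stringsAsFactors = FALSE)
  if (anyDuplicated(paste(out$snp_id, out$trait_gene, sep = "\r")))
    stop("duplicate (SNP, trait) record(s) in ", path)
  attr(out, "nDropped") <- nDropped
  out
}

#' Read two-locus (SNP pair) association results
#'
#' Header-keyed per the dialect (`SNP1`, `SNP2`, `TRAIT`, `P` by default,
#' mirroring PLINK epistasis output plus an explicit trait column). SNP pairs
#' are canonicalized by sorting the two ids, so (a,b) and (b,a) records
#' coincide; exact duplicate records collapse with a warning; records pairing
#' a SNP with itself or with `P` out of [0,1] are rejected with a warning.
#'
#' @inheritParams readGenotypeTable
#' @return data.frame with columns `snp_a`, `snp_b` (sorted), `trait_gene`,
#'   `p`; attributes `nRejected` and `nDuplicates` carry the counts.
#' @export
readPairResults <- function(path, dialect = ioDialect()) {
  df <- readTsvChar(path)
  cols <- dialect$pair
  assertColumns(df, cols, path)
  s1 <- trimws(df[[cols$snp1]]); s2 <- trimws(df[[cols$snp2]])
  p <- suppressWarnings(as.numeric(df[[cols$p]]))
  selfPair <- s1 == s2
  badP <- is.na(p) | p < 0 | p > 1
  nRejected <- sum(selfPair | badP)
  if (nRejected)
    warning(nRejected, " record(s) rejected (self-pair or bad P) in ", path)
  keep <- !selfPair & !badP
  out <- data.frame(snp_a = pmin(s1, s2)[keep], snp_b = pmax(s1, s2)[keep],
                    trait_gene = trimws(df[[cols$trait]])[keep], p = p[keep],
                    stringsAsFactors = FALSE)
  key <- paste(out$snp_a, out$snp_b, out$trait_gene, out$p, sep = "\r")
  nDup <- sum(duplicated(key))
  if (nDup) {
    warning(nDup, " exact duplicate record(s) collapsed in ", path)
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "nRejected") <- nRejected
  attr(out, "nDuplicates") <- nDup
  out
}
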