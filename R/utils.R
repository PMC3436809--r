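# Shared internal helpers: allele-call canonicalization, SNP id parsing,
# tab-separated reading with the package-wide conventions.

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonicalize raw genotype tokens
#'
#' Turns raw genotype cell tokens ("AC", "c/a", "A C", ...) into canonical
#' unordered allele pairs stored as two-character strings with the alleles in
#' alphabetical order ("AC"), so that "CA" and "AC" compare equal. Tokens in
#' `missingTokens` and anything unparseable become `NA` (a missing call);
#' the counts of both are attached as attributes `nMissing` and
#' `nUnparseable`.
#'
#' @param x character vector of raw genotype tokens.
#' @param missingTokens tokens denoting a missing call.
#' @return character vector of canonical calls (or `NA`), with attributes
#'   `nMissing` and `nUnparseable`.
#' @examples
#' parseCalls(c("CA", "ac", "00", "XY"))
#' @export
parseCalls <- function(x, missingTokens = c("00", "NN", "--", "")) {
  x0 <- toupper(gsub("[/ ]", "", trimws(as.character(x))))
  x0[is.na(x)] <- ""
  out <- rep(NA_character_, length(x0))
  isMissing <- x0 %in% toupper(missingTokens)
  ok <- !isMissing & grepl("^[ACGT]{2}$", x0)
  if (any(ok)) {
    a1 <- substr(x0[ok], 1L, 1L)
    a2 <- substr(x0[ok], 2L, 2L)
    out[ok] <- paste0(pmin(a1, a2), pmax(a1, a2))
  }
  attr(out, "nMissing") <- sum(isMissing)
  attr(out, "nUnparseable") <- sum(!isMissing & !ok)
  out
}

# Unordered SNP-pair key, stable under argument order.
canonicalPairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Parse "chr1:150"-style SNP identifiers into (chrom, pos); ids without a
# parseable position (e.g. rs numbers) yield NA coordinates.
parseSnpPositions <- function(ids) {
  m <- regmatches(ids, regexec("^([^:[:space:]]+):([0-9]+)$", ids))
  chrom <- vapply(m, function(g) if (length(g) == 3L) g[2L] else NA_character_, "")
  pos <- vapply(m, function(g) if (length(g) == 3L) as.numeric(g[3L]) else NA_real_, 0)
  data.frame(snp_id = ids, chrom = chrom, pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

# Tab-separated read with '#'-comment lines ignored; all columns character.
readTsvChar <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = header,
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", blank.lines.skip = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  df
}

assertColumns <- function(df, wanted, path) {
  missing <- setdiff(unlist(wanted), names(df))
  if (length(missing)) {
    stop("missing mandatory column(s) ", paste(missing, collapse = ", "),
         " in ", path, "; found headers: ", paste(names(df), collapse = ", "))
  }
}

# Numeric coercion that reports which values failed.
asNumericChecked <- function(x) {
  y <- suppressWarnings(as.numeric(x))
  attr(y, "bad") <- which(is.na(y) & !is.na(x) & toupper(trimws(x)) != "NA")
  y
}

# Fixed-format numbers for byte-stable file output; full round-trip precision.
formatNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

writeTsvLines <- function(header, body, path) {
  con <- file(path, open = "wb")  # avoid platform newline translation
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
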