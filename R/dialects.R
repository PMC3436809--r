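#' File dialects for tab-separated cohort and result tables
#'
#' Input files vary in column naming between toolchains. A *dialect* names,
#' for each table kind, the headers that hold each field, the tokens that
#' denote a missing genotype call, and the phenotype status coding. Parsing is
#' header-keyed throughout, so column order never matters. Two dialects ship
#' with the package:
#'
#' * `"contest"` (default): `FID`/`IID`/`STATUS` phenotype columns, result
#'   columns `SNP`/`TRAIT`/`P`/`R2` and `SNP1`/`SNP2`/`TRAIT`/`P`.
#' * `"plink"`: identical except the phenotype status column is `PHENOTYPE`,
#'   the convention of PLINK `.fam`-derived tables.
#'
#' Both use the PLINK affection coding (2 = affected, 1 = unaffected). Every
#' entry can be overridden via [readDialectConfig()] or by editing the
#' returned list.
#'
#' @param name dialect name, `"contest"` or `"plink"`.
#' @return a named list with entries `missing_tokens`, `phenotype`
#'   (`family`, `individual`, `status` column names), `status_map` (named
#'   character vector token -> group), `single` and `pair` (result-file
#'   column names).
#' @examples
#' ioDialect("plink")$phenotype$status
#' @export
ioDialect <- function(name = c("contest", "plink")) {
  name <- match.arg(name)
  d <- list(
    name = name,
    missing_tokens = c("00", "NN", "--", ""),
    phenotype = list(family = "FID", individual = "IID", status = "STATUS"),
    status_map = c("2" = "affected", "1" = "unaffected"),
    single = list(snp = "SNP", trait = "TRAIT", p = "P", r2 = "R2"),
    pair = list(snp1 = "SNP1", snp2 = "SNP2", trait = "TRAIT", p = "P")
  )
  if (name == "plink") d$phenotype$status <- "PHENOTYPE"
  d
}

#' Read dialect overrides from a plain-text config file
#'
#' The config file holds one `key = value` pair per line (`#` comments
#' allowed). Dotted keys address nested entries, e.g.
#' `phenotype.status = Affection` or `single.r2 = RSQ`. Comma-separated
#' values become vectors (`missing_tokens = 00,NN,.`); the `status_map` key
#' takes `token:group` pairs (`status_map = 2:affected,1:unaffected`).
#'
#' @param path config file path.
#' @param base dialect to start from (default `"contest"`).
#' @return a dialect list as from [ioDialect()], with overrides applied.
#' @export
readDialectConfig <- function(path, base = ioDialect("contest")) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  d <- base
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1L]]
    if (length(kv) != 3L) stop("cannot parse config line: ", ln)
    key <- trimws(kv[2L]); val <- trimws(kv[3L])
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    if (identical(parts[1L], "status_map")) {
      sm <- strsplit(vals, ":", fixed = TRUE)
      tokens <- vapply(sm, `[`, "", 1L)
      groups <- vapply(sm, `[`, "", 2L)
      if (!all(groups %in% c("affected", "unaffected"))) {
        stop("status_map groups must be 'affected' or 'unaffected'")
      }
      d$status_map <- stats::setNames(groups, tokens)
    } else if (length(parts) == 1L) {
      d[[parts]] <- vals
    } else if (length(parts) == 2L) {
      d[[parts[1L]]][[parts[2L]]] <- vals
    } else {
      stop("config key too deep: ", key)
    }
  }
  d
}
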