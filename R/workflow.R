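# End-to-end workflow: parse -> map SNPs -> build graph -> single-locus
# filter -> pair restriction -> tau display filter -> genotype summaries,
# relevance rule and chi-squared -> expression statistics -> renderings,
# with a machine-readable summary of every cascade count.

#' Assemble a workflow configuration
#'
#' Paths to the six input tables plus the thresholds of the filter cascade.
#' Thresholds default to the canonical analysis values: pair significance
#' `alpha` 0.05, single-locus gate `r2Min` 0.1 / `pMax` 0.05, display edge
#' weight `tau` 50, relevance margin `delta` 0.10.
#'
#' @param genotypes,expression,phenotypes,reference,loci,single,pairs input
#'   file paths.
#' @param outDir output directory.
#' @param alpha,r2Min,pMax,tau,delta cascade thresholds.
#' @param dialect a dialect list from [ioDialect()] or
#'   [readDialectConfig()].
#' @param focusPatient patient id for the genotype view's individual row
#'   (default: first patient).
#' @param viewFromTauGraph derive the genotype-view SNP set from the
#'   tau-filtered graph instead of the full restriction cascade. By default
#'   `tau` thins the displayed/exported edges only; the analyzed SNP set is
#'   every SNP in the restricted pair list.
#' @param layoutSeed seed for the graph layout.
#' @return a `runConfig` list.
#' @export
runConfig <- function(genotypes, expression, phenotypes, reference, loci,
                      single, pairs, outDir,
                      alpha = 0.05, r2Min = 0.1, pMax = 0.05, tau = 50L,
                      delta = 0.10, dialect = ioDialect(),
                      focusPatient = NULL, viewFromTauGraph = FALSE,
                      layoutSeed = 1L) {
  stopifnot(alpha > 0, alpha <= 1, r2Min >= 0, r2Min <= 1,
            pMax >= 0, pMax <= 1, tau >= 0, delta >= 0, delta <= 1)
  structure(list(genotypes = genotypes, expression = expression,
                 phenotypes = phenotypes, reference = reference,
                 loci = loci, single = single, pairs = pairs,
                 outDir = outDir, alpha = alpha, r2Min = r2Min,
                 pMax = pMax, tau = as.integer(tau), delta = delta,
                 dialect = dialect, focusPatient = focusPatient,
                 viewFromTauGraph = viewFromTauGraph,
                 layoutSeed = as.integer(layoutSeed)),
            class = "runConfig")
}

#' Read a workflow configuration file
#'
#' Plain-text `key = value` lines naming the [runConfig()] arguments
#' (file paths and thresholds); `#` comments allowed. Relative paths are
#' resolved against the config file's directory.
#'
#' @param path config file.
#' @param ... overrides passed on to [runConfig()].
#' @return a `runConfig` list.
#' @export
readRunConfig <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  args <- stats::setNames(
    lapply(kv, function(m) trimws(m[3L])),
    vapply(kv, function(m) trimws(m[2L]), ""))
  fileKeys <- c("genotypes", "expression", "phenotypes", "reference",
                "loci", "single", "pairs", "outDir")
  numKeys <- c("alpha", "r2Min", "pMax", "tau", "delta", "layoutSeed")
  base <- dirname(normalizePath(path))
  for (k in intersect(fileKeys, names(args))) {
    v <- args[[k]]
    if (!grepl("^/", v)) args[[k]] <- file.path(base, v)
  }
  for (k in intersect(numKeys, names(args))) args[[k]] <- as.numeric(args[[k]])
  if ("viewFromTauGraph" %in% names(args))
    args$viewFromTauGraph <- toupper(args$viewFromTauGraph) %in%
      c("TRUE", "1", "YES")
  over <- list(...)
  args[names(over)] <- over
  do.call(runConfig, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("workflow stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis workflow
#'
#' Executes the complete cascade on the six input files and writes graph
#' exports (GraphML, DOT, edge list), the genotype-view table and image,
#' the gene statistics table, full and aggregated heatmaps, and a
#' machine-readable `summary.json` with every cascade count. Any stage
#' error aborts with the stage name; partially written outputs are removed.
#'
#' @param config a `runConfig` list from [runConfig()] or
#'   [readRunConfig()].
#' @param render write SVG figures (disable for table-only runs).
#' @return the summary list, invisibly; side effect: files in
#'   `config$outDir`.
#' @export
runWorkflow <- function(config, render = TRUE) {
  stopifnot(inherits(config, "runConfig"))
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  out <- function(name) {
    p <- file.path(outDir, name)
    written <<- c(written, p)
    p
  }
  onFail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    d <- config$dialect
    gm <- stage("parse genotypes", readGenotypeTable(config$genotypes, d))
    patients <- stage("parse phenotypes",
                      readPhenotypeTable(config$phenotypes, d))
    expr <- stage("parse expression", readExpressionTable(config$expression))
    refs <- stage("parse reference", readReferenceTable(config$reference))
    loci <- stage("parse loci", readGeneLoci(config$loci))
    single <- stage("parse single-locus results",
                    readSingleLocusResults(config$single, d))
    pairs <- stage("parse pair results", readPairResults(config$pairs, d))

    map <- stage("map SNPs to genes", assignSnpsToGenes(gm, loci))

    keep <- stage("single-locus filter",
                  significantSingleLocusSnps(single, config$r2Min,
                                             config$pMax))
    restricted <- stage("pair restriction",
                        restrictPairsToSnpSet(pairs, keep))
    graph <- stage("build graph",
                   buildAssociationGraph(restricted, map, loci,
                                         alpha = config$alpha))
    graph <- assignNodeColors(graph)
    shown <- stage("tau filter", filterEdgesByWeight(graph, config$tau))
    stage("export graph", {
      exportGraph(shown, out("graph.graphml"), "graphml")
      exportGraph(shown, out("graph.dot"), "dot")
      writeEdgeList(shown, out("edges.tsv"))
    })

    # SNPs analyzed in the genotype view: significant mapped pairs of the
    # restricted list (optionally only those on tau-surviving edges)
    sigRestricted <- restricted[restricted$p < config$alpha, , drop = FALSE]
    viewSource <- if (config$viewFromTauGraph) {
      prs <- unique(unlist(edgeProvenance(shown), use.names = FALSE))
      if (length(prs)) {
        sp <- strsplit(prs, "|", fixed = TRUE)
        data.frame(snp_a = vapply(sp, `[`, "", 1L),
                   snp_b = vapply(sp, `[`, "", 2L))
      } else data.frame(snp_a = character(), snp_b = character())
    } else sigRestricted
    viewSnps <- stage("collect view SNPs", snpsInPairs(viewSource))
    viewSnps <- viewSnps[viewSnps %in% snpIds(gm)]

    summ <- stage("genotype summaries",
                  summarizeGenotypes(gm, patients, viewSnps, refs))
    relevant <- stage("relevance rule",
                      detectRelevantSnps(summ, delta = config$delta))
    chi2 <- stage("chi-squared tests", chi2PerSnp(gm, patients, viewSnps))
    chi2Hits <- chi2$snp_id[chi2$p < 0.05 & !chi2$degenerate]
    view <- stage("genotype view model",
                  buildGenotypeViewModel(
                    viewSnps, gm, patients, refs, single,
                    focusPatient = config$focusPatient %||%
                      patients$patient_id[1L],
                    delta = config$delta))
    stage("write view table", writeGenotypeViewTable(view,
                                                     out("genotype_view.tsv")))

    stats <- stage("expression statistics", geneStats(expr, patients))
    stage("write gene stats", writeGeneStats(stats, out("gene_stats.tsv")))

    if (render) stage("render figures", {
      renderAssociationGraph(shown, out("graph.svg"),
                             layoutSeed = config$layoutSeed)
      if (nrow(view)) renderGenotypeView(view, out("genotype_view.svg"))
      renderHeatmap(expr, stats, patients, out("heatmap.svg"))
      renderHeatmap(expr, stats, patients, out("heatmap_aggregated.svg"),
                    aggregate = TRUE)
    })

    et <- edgeTable(graph)
    summary <- list(
      n_pairs_in = nrow(pairs),
      n_pairs_after_restriction = nrow(restricted),
      n_significant_pairs = graphMeta(graph)$nSignificant,
      n_pairs_skipped_unassigned = graphMeta(graph)$nSkippedUnassigned,
      n_snps_genotyped = length(snpIds(gm)),
      n_snps_single_locus_pass = length(keep),
      n_snps_in_network = length(viewSnps),
      n_edges = nrow(et),
      n_edges_shown = nrow(edgeTable(shown)),
      total_edge_weight = sum(et$weight),
      max_edge_weight = if (nrow(et)) max(et$weight) else 0L,
      n_relevant_snps = length(relevant),
      n_chi2_rejections = length(chi2Hits),
      n_relevant_and_chi2 = length(intersect(relevant, chi2Hits)),
      thresholds = config[c("alpha", "r2Min", "pMax", "tau", "delta")])
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(summary)
  }, error = onFail)
}
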