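# Fixture mirroring the documented construction example: SNPs s1 in gene A,
# s2 and s3 in gene B; traits C and D.
exampleInstance <- function() {
  loci <- data.frame(gene = c("A", "B", "C", "D"), chrom = "chr1",
                     start = c(1L, 101L, 201L, 301L),
                     end = c(100L, 200L, 300L, 400L))
  snps <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "chr1",
                     pos = c(50L, 150L, 160L))
  map <- assignSnpsToGenes(snps, loci)
  pairs <- data.frame(snp_a = c("s1", "s1", "s1"),
                      snp_b = c("s2", "s3", "s2"),
                      trait_gene = c("C", "C", "D"),
                      p = c(0.01, 0.02, 0.01), stringsAsFactors = FALSE)
  list(loci = loci, map = map, pairs = pairs)
}

test_that("edges accumulate one unit per distinct SNP pair and color", {
  inst <- exampleInstance()
  g <- buildAssociationGraph(inst$pairs, inst$map, inst$loci)
  e <- edgeTable(g)
  expect_equal(nrow(e), 2L)
  expect_equal(e$weight[e$color_gene == "C"], 2L)
  expect_equal(e$weight[e$color_gene == "D"], 1L)
  expect_equal(unique(e$gene_a), "A")
  expect_equal(unique(e$gene_b), "B")
  nt <- nodeTable(g)
  expect_equal(nt$colored, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(length(g@nodes), 4L)  # full locus table, isolated nodes kept
  expect_false(any(e$cis))
})

test_that("the significance threshold is strict and empties the graph", {
  inst <- exampleInstance()
  inst$pairs$p <- 0.2
  g <- buildAssociationGraph(inst$pairs, inst$map, inst$loci)
  expect_equal(nrow(edgeTable(g)), 0L)
  expect_equal(length(g@nodes), 4L)
  # boundary: p exactly alpha is excluded unless inclusive
  inst$pairs$p <- 0.05
  expect_equal(nrow(edgeTable(
    buildAssociationGraph(inst$pairs, inst$map, inst$loci))), 0L)
  expect_equal(nrow(edgeTable(
    buildAssociationGraph(inst$pairs, inst$map, inst$loci,
                          inclusive = TRUE))), 2L)
})

test_that("unassigned SNPs skip pairs; unknown traits error", {
  inst <- exampleInstance()
  asn <- geneAssignments(inst$map)
  asn[["s3"]] <- NA_character_
  map <- new("SnpGeneMap", assignments = asn,
             distances = snpDistances(inst$map), ties = assignmentTies(inst$map))
  g <- buildAssociationGraph(inst$pairs, map, inst$loci)
  expect_equal(graphMeta(g)$nSkippedUnassigned, 1L)
  expect_equal(sum(edgeTable(g)$weight), 2L)
  inst$pairs$trait_gene[1] <- "Z"
  expect_error(buildAssociationGraph(inst$pairs, inst$map, inst$loci),
               "absent from locus table")
})

test_that("self-loops and cis effects are representable and flagged", {
  inst <- exampleInstance()
  pairs <- data.frame(snp_a = "s2", snp_b = "s3", trait_gene = c("B", "C"),
                      p = 0.01)
  g <- buildAssociationGraph(pairs, inst$map, inst$loci)
  e <- edgeTable(g)
  expect_equal(e$gene_a, c("B", "B"))
  expect_equal(e$gene_b, c("B", "B"))                    # self-loop
  expect_equal(e$cis, c(TRUE, FALSE))                    # B-colored is cis
  expect_equal(unname(nodeDegree(g)[["B"]]), 2L)         # self-loop counts 1
})

test_that("edge weights match the brute-force triple count", {
  set.seed(202)
  for (rep in 1:25) {
    inst <- randomGraphInstance(sample(2:10, 1), 30, sample(20:200, 1))
    g <- buildAssociationGraph(inst$pairs, inst$map, inst$loci, alpha = 0.3)
    bf <- bruteForceEdgeWeights(inst$pairs, geneAssignments(inst$map),
                                alpha = 0.3)
    e <- edgeTable(g)
    keys <- paste(e$gene_a, e$gene_b, e$color_gene, sep = "\r")
    bfKeys <- if (is.null(names(bf))) character(0) else names(bf)
    expect_setequal(keys, bfKeys)
    expect_equal(e$weight[match(bfKeys, keys)],
                 as.integer(unlist(bf, use.names = FALSE)) %||% integer(0))
  }
})

test_that("weight per color conserves the significant mapped pair count", {
  set.seed(303)
  inst <- randomGraphInstance(6, 40, 150)
  g <- buildAssociationGraph(inst$pairs, inst$map, inst$loci, alpha = 0.4)
  e <- edgeTable(g)
  asn <- geneAssignments(inst$map)
  sig <- inst$pairs[inst$pairs$p < 0.4 &
                    !is.na(asn[inst$pairs$snp_a]) &
                    !is.na(asn[inst$pairs$snp_b]), ]
  sig <- sig[!duplicated(paste(sig$snp_a, sig$snp_b, sig$trait_gene)), ]
  perColor <- table(sig$trait_gene)
  got <- tapply(e$weight, e$color_gene, sum)
  expect_equal(as.integer(got[names(perColor)]), as.integer(perColor))
  expect_equal(sum(e$weight), nrow(sig))
})

test_that("tau filtering keeps nodes and colored flags, drops light edges", {
  inst <- exampleInstance()
  g <- buildAssociationGraph(inst$pairs, inst$map, inst$loci)
  f2 <- filterEdgesByWeight(g, 2L)
  expect_equal(nrow(edgeTable(f2)), 1L)
  expect_equal(edgeTable(f2)$weight, 2L)
  expect_equal(length(f2@nodes), 4L)
  expect_identical(f2@colored, g@colored)   # display filter, not semantics
  expect_identical(edgeTable(filterEdgesByWeight(g, 0L)), edgeTable(g))
  fBig <- filterEdgesByWeight(g, 99L)
  expect_equal(nrow(edgeTable(fBig)), 0L)
  expect_equal(length(fBig@nodes), 4L)
})

test_that("single-locus gate is strict at both thresholds", {
  res <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                    trait_gene = "g",
                    p = c(0.01, 0.01, 0.2, 0.01),
                    r2 = c(0.2, 0.05, 0.2, 0.1))
  expect_equal(significantSingleLocusSnps(res), "s1")  # s4 at r2=0.1 excluded
})

test_that("pair restriction and the SNP census behave like set operations", {
  pairs <- data.frame(snp_a = c("s1", "s3"), snp_b = c("s2", "s4"),
                      trait_gene = "g", p = 0.01)
  expect_equal(restrictPairsToSnpSet(pairs, "s1")$snp_b, "s2")
  expect_equal(nrow(restrictPairsToSnpSet(pairs, character())), 0L)
  expect_equal(restrictPairsToSnpSet(pairs, c("s1", "s2", "s3", "s4")),
               pairs, ignore_attr = TRUE)
  expect_equal(snpsInPairs(pairs), c("s1", "s2", "s3", "s4"))
  expect_equal(snpsInPairs(pairs[0, ]), character())
})

test_that("pairs-per-SNP counts satisfy the handshake identity", {
  pairs <- data.frame(snp_a = c("s1", "s1"), snp_b = c("s2", "s3"),
                      trait_gene = "g", p = 0.01)
  cnt <- pairsPerSnp(pairs, c("s1", "s2", "s9"))
  expect_equal(cnt, c(s1 = 2L, s2 = 1L, s9 = 0L))
  all <- pairsPerSnp(pairs, snpsInPairs(pairs))
  expect_equal(sum(all), 2L * nrow(pairs))
})

test_that("node degree counts multi-edges separately unless merged", {
  inst <- exampleInstance()
  g <- buildAssociationGraph(inst$pairs, inst$map, inst$loci)
  deg <- nodeDegree(g)
  expect_equal(unname(deg[c("A", "B", "C", "D")]), c(2L, 2L, 0L, 0L))
  expect_equal(unname(nodeDegree(g, mergeMultiEdges = TRUE)[["A"]]), 1L)
})

test_that("node colors assign alphabetically and recycle with a warning", {
  inst <- exampleInstance()
  g <- buildAssociationGraph(inst$pairs, inst$map, inst$loci)
  pal <- c("#111111", "#222222")
  gc <- assignNodeColors(g, pal)
  expect_equal(unname(gc@colors[c("C", "D")]), pal)
  expect_equal(unname(gc@colors[["A"]]), "#BEBEBE")
  expect_warning(assignNodeColors(g, "#111111"), "repeat")
  gAllGray <- buildAssociationGraph(inst$pairs[0, ], inst$map, inst$loci)
  expect_true(all(assignNodeColors(gAllGray)@colors == "#BEBEBE"))
})

test_that("graph construction ignores input row order", {
  set.seed(404)
  inst <- randomGraphInstance(5, 25, 80)
  g1 <- buildAssociationGraph(inst$pairs, inst$map, inst$loci, alpha = 0.3)
  g2 <- buildAssociationGraph(inst$pairs[sample.int(nrow(inst$pairs)), ],
                              inst$map, inst$loci, alpha = 0.3)
  expect_identical(edgeTable(g1), edgeTable(g2))
  expect_identical(lapply(edgeProvenance(g1), sort),
                   lapply(edgeProvenance(g2), sort))
})
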