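test_that("genotype tables parse with canonical unordered allele pairs", {
  f <- writeTempTsv(c("patient\ts1\ts2\ts3",
                      "P1\tAA\tCA\t00",
                      "P2\tAA\tAC\tXY"))
  gm <- readGenotypeTable(f)
  expect_equal(dim(gm), c(2L, 3L))
  expect_equal(snpCalls(gm)["P1", "s2"], snpCalls(gm)["P2", "s2"])
  expect_equal(snpCalls(gm)["P1", "s2"], "AC")
  expect_true(is.na(snpCalls(gm)["P1", "s3"]))   # dialect missing token
  expect_true(is.na(snpCalls(gm)["P2", "s3"]))   # unparseable
  expect_equal(parseReport(gm)$nMissing, 1L)
  expect_equal(parseReport(gm)$nUnparseable, 1L)
})

test_that("genotype reader rejects malformed tables", {
  dup <- writeTempTsv(c("patient\ts1", "P1\tAA", "P1\tAC"))
  expect_error(readGenotypeTable(dup), "duplicate patient")
  dupSnp <- writeTempTsv(c("patient\ts1\ts1", "P1\tAA\tAC"))
  expect_error(readGenotypeTable(dupSnp), "duplicate SNP")
  empty <- writeTempTsv("patient\ts1")
  expect_error(readGenotypeTable(empty), "empty")
})

test_that("phenotype tables map status tokens and validate identity", {
  f <- writeTempTsv(c("FID\tIID\tSTATUS",
                      "F1\tI1\t2", "F2\tI2\t1", "F3\tI3\t1"))
  p <- readPhenotypeTable(f)
  expect_equal(as.character(p$group),
               c("affected", "unaffected", "unaffected"))
  bad <- writeTempTsv(c("FID\tIID\tSTATUS", "F1\tI1\t2", "F2\tI2\t"))
  expect_error(readPhenotypeTable(bad), "row 2")
  dup <- writeTempTsv(c("FID\tIID\tSTATUS", "F1\tI1\t2", "F1\tI1\t1"))
  expect_error(readPhenotypeTable(dup), "duplicate \\(family, individual\\)")
})

test_that("expression tables parse both orientations and catch bad cells", {
  f <- writeTempTsv(c("gene\tP1\tP2\tP3",
                      "g1\t0\t0\t0", "g2\t1e-2\t0\t0"))
  e <- readExpressionTable(f)
  expect_equal(dim(e), c(2L, 3L))
  expect_equal(e["g2", "P1"], 0.01)
  ft <- writeTempTsv(c("patient\tg1\tg2",
                       "P1\t0\t1e-2", "P2\t0\t0", "P3\t0\t0"))
  expect_equal(readExpressionTable(ft, patientsInRows = TRUE), e)
  bad <- writeTempTsv(c("gene\tP1", "g1\tx2"))
  expect_error(readExpressionTable(bad), "g1.*P1")
  ragged <- writeTempTsv(c("gene\tP1\tP2", "g1\t1\t2", "g2\t1"))
  expect_error(readExpressionTable(ragged), "ragged")
})

test_that("reference tables uppercase, deduplicate and validate bases", {
  f <- writeTempTsv(c("s1\tA", "s2\tc", "s1\tA"))
  refs <- readReferenceTable(f)
  expect_equal(refs, c(s1 = "A", s2 = "C"))
  expect_error(readReferenceTable(writeTempTsv("s1\tN")), "invalid")
  expect_error(readReferenceTable(writeTempTsv(c("s1\tA", "s1\tC"))),
               "conflicting")
})

test_that("gene loci read as GRanges, including BED conversion", {
  f <- writeTempTsv(c("gene\tchrom\tstart\tend",
                      "A\tchr1\t100\t200", "B\tchr2\t50\t60"))
  gr <- readGeneLoci(f)
  expect_s4_class(gr, "GRanges")
  expect_equal(names(gr), c("A", "B"))
  expect_equal(GenomicRanges::start(gr), c(100L, 50L))
  bed <- writeTempTsv(c("chr1\t99\t200\tA", "chr2\t49\t60\tB"))
  expect_equal(readGeneLoci(bed, bed = TRUE), gr)
  expect_error(readGeneLoci(writeTempTsv("A\tchr1\t5\t2")), "start > end")
})

test_that("single-locus results drop bad rows and are column-order free", {
  f <- writeTempTsv(c("SNP\tTRAIT\tP\tR2",
                      "s1\tg1\t0.04\t0.2",
                      "s2\tg1\tNA\t0.3",
                      "s3\tg1\t0.5\t0.01"))
  expect_warning(res <- readSingleLocusResults(f), "1 row")
  expect_equal(nrow(res), 2L)
  expect_equal(res$p[res$snp_id == "s1"], 0.04)
  expect_equal(res$r2[res$snp_id == "s1"], 0.2)
  reordered <- writeTempTsv(c("R2\tP\tSNP\tTRAIT",
                              "0.2\t0.04\ts1\tg1",
                              "0.3\tNA\ts2\tg1",
                              "0.01\t0.5\ts3\tg1"))
  expect_warning(res2 <- readSingleLocusResults(reordered))
  expect_equal(res2, res, ignore_attr = TRUE)
  noCol <- writeTempTsv(c("SNP\tP\tR2", "s1\t0.1\t0.1"))
  expect_error(readSingleLocusResults(noCol), "TRAIT")
})

test_that("pair results canonicalize, deduplicate and bound-check", {
  f <- writeTempTsv(c("SNP1\tSNP2\tTRAIT\tP",
                      "s1\ts2\tG\t0.01",
                      "s2\ts1\tG\t0.01",    # same canonical record
                      "s3\ts4\tG\t0.02",
                      "s5\ts5\tG\t0.01",    # self pair
                      "s6\ts7\tG\t1.5"))    # out of bounds
  expect_warning(expect_warning(res <- readPairResults(f)))
  expect_equal(nrow(res), 2L)
  expect_true(all(res$snp_a <= res$snp_b))
  expect_equal(attr(res, "nRejected"), 2L)
  expect_equal(attr(res, "nDuplicates"), 1L)
})

test_that("row permutation does not change parsed results", {
  header <- "SNP1\tSNP2\tTRAIT\tP"
  rows <- sprintf("s%d\ts%d\tG\t0.0%d", 1:4, 5:8, 1:4)
  set.seed(1)
  a <- readPairResults(writeTempTsv(c(header, rows)))
  b <- readPairResults(writeTempTsv(c(header, sample(rows))))
  ord <- function(d) d[order(d$snp_a, d$snp_b, d$trait_gene), ]
  expect_equal(ord(a), ord(b), ignore_attr = TRUE)
})

test_that("dialect config files override nested entries", {
  f <- writeTempTsv(c("# custom layout",
                      "phenotype.status = Affection",
                      "missing_tokens = 00,./.",
                      "status_map = case:affected,ctrl:unaffected"))
  d <- readDialectConfig(f)
  expect_equal(d$phenotype$status, "Affection")
  expect_equal(d$missing_tokens, c("00", "./."))
  ph <- writeTempTsv(c("FID\tIID\tAffection", "F1\tI1\tcase", "F2\tI2\tctrl"))
  p <- readPhenotypeTable(ph, d)
  expect_equal(as.character(p$group), c("affected", "unaffected"))
})

test_that("graph export writes valid GraphML/DOT with multi-edges", {
  inst <- local({set.seed(42); randomGraphInstance(5, 20, 40)})
  g <- buildAssociationGraph(inst$pairs, inst$map, inst$loci, alpha = 0.5)
  f <- tempfile(fileext = ".graphml")
  exportGraph(g, f, "graphml")
  back <- importGraphML(f)
  expect_equal(back$nodes, nodeTable(g)[order(nodeTable(g)$gene), ],
               ignore_attr = TRUE)
  et <- edgeTable(g)
  expect_equal(back$edges[order(back$edges$gene_a, back$edges$gene_b,
                                back$edges$color_gene), ],
               et[order(et$gene_a, et$gene_b, et$color_gene), ],
               ignore_attr = TRUE)
  fdot <- tempfile(fileext = ".dot")
  exportGraph(g, fdot, "dot")
  expect_true(any(grepl("color_gene", readLines(fdot))))
  # empty graph still exports
  g0 <- filterEdgesByWeight(g, 1e6L)
  f0 <- tempfile(fileext = ".graphml")
  exportGraph(g0, f0)
  expect_equal(nrow(importGraphML(f0)$edges), 0L)
  expect_equal(nrow(importGraphML(f0)$nodes), length(inst$genes))
  expect_error(exportGraph(g, tempfile(), "gexf"))
})
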