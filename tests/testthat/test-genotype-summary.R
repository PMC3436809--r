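test_that("genotype simplification counts non-reference alleles", {
  expect_equal(as.character(simplifyGenotype(c("AA", "AC", "CC", "CG", NA),
                                             "A")),
               c("REF", "HET", "HOM", "HOM", NA))
})

test_that("group summaries compute distribution, consensus and strength", {
  codes <- matrix(c(rep(0L, 6), rep(1L, 3), 2L,     # affected: 6/3/1
                    rep(0L, 5), rep(1L, 5)),        # unaffected: 5/5
                  ncol = 1, dimnames = list(sprintf("P%03d", 1:20), "s1"))
  gm <- gmFromCodes(codes)
  pats <- makePatients(10, 10)
  s <- summarizeGenotypes(gm, pats, "s1", c(s1 = "A"))
  aff <- s[s$group == "affected", ]
  expect_equal(aff$consensus, "REF")
  expect_equal(aff$strength, 0.6)
  expect_equal(aff[, c("n_ref", "n_het", "n_hom")],
               data.frame(n_ref = 6L, n_het = 3L, n_hom = 1L),
               ignore_attr = TRUE)
  expect_equal(aff$dist[[1]], c(AA = 6L, AC = 3L, CC = 1L))
  una <- s[s$group == "unaffected", ]
  expect_equal(una$consensus, "REF")   # 5/5 tie breaks REF < HET < HOM
  expect_equal(una$strength, 0.5)
})

test_that("fully missing groups yield an undefined consensus", {
  codes <- matrix(c(rep(NA_integer_, 5), rep(1L, 5)), ncol = 1,
                  dimnames = list(sprintf("P%03d", 1:10), "s1"))
  gm <- gmFromCodes(codes)
  s <- summarizeGenotypes(gm, makePatients(5, 5), "s1", c(s1 = "A"))
  aff <- s[s$group == "affected", ]
  expect_equal(aff$n_missing, 5L)
  expect_true(is.na(aff$consensus))
  expect_equal(aff$strength, 0)
})

test_that("count conservation holds for every SNP and group", {
  set.seed(21)
  codes <- matrix(sample(c(0:2, NA), 200, replace = TRUE), nrow = 20,
                  dimnames = list(sprintf("P%03d", 1:20),
                                  sprintf("s%d", 1:10)))
  gm <- gmFromCodes(codes)
  pats <- makePatients(12, 8)
  s <- summarizeGenotypes(gm, pats, refs = setNames(rep("A", 10),
                                                    sprintf("s%d", 1:10)))
  expect_true(all(s$n_ref + s$n_het + s$n_hom + s$n_missing == s$n))
  expect_true(all(s$n[s$group == "affected"] == 12L))
  # strength is the majority fraction of non-missing patients
  nonMiss <- s$n - s$n_missing
  obs <- pmax(s$n_ref, s$n_het, s$n_hom)
  expect_equal(s$strength[nonMiss > 0], (obs / nonMiss)[nonMiss > 0])
})

test_that("relevance rule: state difference or >= 10-point strength gap", {
  mkSumm <- function(stateA, strA, stateU, strU) {
    data.frame(snp_id = "s", group = c("affected", "unaffected"),
               n = 10L, n_missing = 0L, n_ref = 1L, n_het = 1L, n_hom = 1L,
               consensus = c(stateA, stateU), strength = c(strA, strU))
  }
  expect_equal(detectRelevantSnps(mkSumm("REF", .8, "HET", .8)), "s",
               ignore_attr = TRUE)
  expect_equal(detectRelevantSnps(mkSumm("REF", .75, "REF", .63)), "s",
               ignore_attr = TRUE)                 # 0.12 >= 0.10
  expect_length(detectRelevantSnps(mkSumm("REF", .75, "REF", .70)), 0)
  # inclusive boundary at exactly 10 points
  expect_equal(detectRelevantSnps(mkSumm("REF", .75, "REF", .65)), "s",
               ignore_attr = TRUE)
  # undefined consensus excludes the SNP and reports it
  out <- detectRelevantSnps(mkSumm(NA, 0, "REF", .6))
  expect_length(out, 0)
  expect_equal(attr(out, "excluded"), "s")
})

test_that("relevance rule degenerates as designed at extreme deltas", {
  set.seed(31)
  summ <- do.call(rbind, lapply(1:30, function(i) {
    data.frame(snp_id = sprintf("s%02d", i), group = c("affected", "unaffected"),
               n = 10L, n_missing = 0L, n_ref = 1L, n_het = 1L, n_hom = 1L,
               consensus = sample(c("REF", "HET"), 2, replace = TRUE),
               strength = runif(2, 0.4, 1))
  }))
  aff <- summ[summ$group == "affected", ]
  una <- summ[summ$group == "unaffected", ]
  # delta > 1: strength clause unsatisfiable -> pure state inequality
  expect_setequal(detectRelevantSnps(summ, delta = 1.01),
                  aff$snp_id[aff$consensus != una$consensus])
  # states forced equal -> pure strength test
  summEq <- summ; summEq$consensus <- "REF"
  expect_setequal(detectRelevantSnps(summEq, delta = 0.10),
                  aff$snp_id[abs(aff$strength - una$strength) >= 0.10 - 1e-12])
})

test_that("Pearson chi-squared matches the hand computation and degenerates", {
  r <- chi2Independence(c(AA = 20, AC = 0), c(AA = 0, AC = 20))
  expect_equal(r$statistic, 40)       # all E = 10, sum (O-E)^2/E = 4*100/10
  expect_equal(r$df, 1L)
  expect_lt(r$p, 1e-9)
  r0 <- chi2Independence(c(AA = 10, AC = 10), c(AA = 10, AC = 10))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  d <- chi2Independence(c(AA = 5), c(AA = 7))
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
  expect_true(chi2Independence(c(AA = 2, AC = 2), c(AA = 2, AC = 1))$caution)
})

test_that("chi-squared agrees with the reference implementation", {
  set.seed(41)
  for (i in 1:60) {
    c1 <- rpois(3, 8); c2 <- rpois(3, 8)
    tab <- rbind(c1, c2)
    keep <- colSums(tab) > 0
    if (sum(keep) < 2 || any(rowSums(tab) == 0)) next
    ours <- chi2Independence(setNames(c1, c("AA", "AC", "CC")),
                             setNames(c2, c("AA", "AC", "CC")))
    ref <- suppressWarnings(
      chisq.test(tab[, keep, drop = FALSE], correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter))
  }
})

test_that("swapping group labels leaves chi2 and relevance unchanged", {
  set.seed(51)
  codes <- matrix(sample(0:2, 300, replace = TRUE, prob = c(.5, .3, .2)),
                  nrow = 30, dimnames = list(sprintf("P%03d", 1:30),
                                             sprintf("s%d", 1:10)))
  gm <- gmFromCodes(codes)
  refs <- setNames(rep("A", 10), sprintf("s%d", 1:10))
  pats <- makePatients(14, 16)
  swapped <- pats
  swapped$group <- factor(ifelse(pats$group == "affected", "unaffected",
                                 "affected"),
                          levels = c("affected", "unaffected"))
  c1 <- chi2PerSnp(gm, pats)
  c2 <- chi2PerSnp(gm, swapped)
  expect_equal(c1$p, c2$p)
  s1 <- summarizeGenotypes(gm, pats, refs = refs)
  s2 <- summarizeGenotypes(gm, swapped, refs = refs)
  expect_setequal(detectRelevantSnps(s1), detectRelevantSnps(s2))
  # summaries themselves swap roles
  a1 <- s1[s1$group == "affected", -2]; u2 <- s2[s2$group == "unaffected", -2]
  expect_equal(a1, u2, ignore_attr = TRUE)
})

test_that("spiked genotype-frequency shifts are recovered with high sensitivity", {
  nRep <- 100L
  hits <- misses <- 0L
  fp <- tested <- 0L
  for (rep in seq_len(nRep)) {
    cfg <- syntheticConfig(nAffected = 250L, nUnaffected = 250L,
                           nSnps = 20L, nGenes = 2L,
                           spikedRelevant = data.frame(snp_id = 1:10,
                                                       shift = 0.15),
                           seed = 7000L + rep)
    ds <- generateDataset(cfg)
    summ <- summarizeGenotypes(ds$genotypes, ds$patients, refs = ds$refs)
    rel <- detectRelevantSnps(summ)
    spiked <- ds$manifest$snp_a[ds$manifest$kind == "relevant"]
    hits <- hits + sum(spiked %in% rel)
    misses <- misses + sum(!spiked %in% rel)
    others <- setdiff(snpIds(ds$genotypes), spiked)
    fp <- fp + sum(others %in% rel)
    tested <- tested + length(others)
  }
  expect_gte(hits / (hits + misses), 0.9)
  expect_lte(fp / tested, 0.15)
})

test_that("the genotype view model orders, clamps and annotates columns", {
  codes <- matrix(rep(0:2, each = 10), nrow = 10,
                  dimnames = list(sprintf("P%03d", 1:10),
                                  c("chr1:300", "chr1:100", "chr1:200")))
  gm <- gmFromCodes(codes)
  pats <- makePatients(5, 5)
  refs <- setNames(rep("A", 3), colnames(codes))
  single <- data.frame(snp_id = rep(colnames(codes), 2),
                       trait_gene = rep(c("g1", "g2"), each = 3),
                       p = c(0.01, 1e-5, 0, 0.5, 0.2, 0.9),
                       r2 = 0.1)
  v <- buildGenotypeViewModel(colnames(codes), gm, pats, refs, single,
                              focusPatient = "P001")
  expect_equal(v$snp_id, c("chr1:100", "chr1:200", "chr1:300"))
  expect_equal(v$neg_log_p[v$snp_id == "chr1:300"], 2)       # p = 0.01
  expect_equal(v$neg_log_p[v$snp_id == "chr1:100"], 5)       # min over traits
  expect_equal(v$best_trait[v$snp_id == "chr1:100"], "g1")
  expect_equal(v$neg_log_p[v$snp_id == "chr1:200"], 300)     # p = 0 clamped
  expect_equal(v$individual_call, c("AC", "CC", "AA"))  # position order
  expect_equal(v$ref_allele, rep("A", 3))
  # majority ordering is available and deterministic
  v2 <- buildGenotypeViewModel(colnames(codes), gm, pats, refs, single,
                               orderBy = "majority")
  expect_setequal(v2$snp_id, v$snp_id)
  f <- tempfile(fileext = ".tsv")
  writeGenotypeViewTable(v, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 3L)
  expect_true("dist_affected" %in% names(tab))
})
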