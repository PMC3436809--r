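---
title: "Association gene networks and cohort genotype summaries for eQTL studies"
author: "eqtlnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association gene networks and cohort genotype summaries for eQTL studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlnet)
```

# The analysis problem

An eQTL (expression quantitative trait locus) cohort combines three kinds of
data per patient: biallelic SNP genotypes (unordered allele pairs, possibly
missing), expression values for a set of genes, and a two-level disease
phenotype (affected / unaffected). Upstream association software — typically
PLINK — tests every SNP, and every pair of SNPs, for association with each
gene's expression, producing single-locus records (p-value and regression
R²) and two-locus records (interaction p-value). The scientific question is
which genes' expression is driven by which genetic variation, and whether
the implicated variants also separate the phenotype groups.

`eqtlnet` implements the analytical core of this workflow as a scriptable
library: building and filtering the association gene network implied by the
two-locus statistics, summarizing cohort genotypes into comparable group
consensus views with per-SNP statistics, and ranking genes by differential
expression. Static SVG/PNG exports replace the interactive displays of
GUI-based predecessors.

# The association gene multigraph

Every gene of the locus table is a node. Each SNP is assigned to its
closest gene (next section). A two-locus record with SNPs in genes
$g_i$ and $g_j$, trait gene $g_k$ and $p < \alpha$ contributes one unit of
weight to the edge keyed by the unordered pair $\{g_i, g_j\}$ *and* the
color gene $g_k$:

$$ w(\{g_i, g_j\},\, g_k) \;=\; \bigl|\{\text{distinct canonical SNP pairs
mapped to } (\{g_i,g_j\},\,g_k)\}\bigr|. $$

Two edges may share endpoints and differ only in color — the graph is a
multigraph. A node is *colored* iff at least one edge carries it as color
gene; the rest are gray. Edges whose color gene is one of their endpoints
are flagged *cis* (variation near a gene associated with that same gene's
expression); all others represent *trans* effects.

The filter cascade applied by `runWorkflow()` is:

1. **Single-locus gate.** Keep SNPs with $R^2 > 0.1$ and $p < 0.05$ for at
   least one trait (`significantSingleLocusSnps()`, strict inequalities;
   an `inclusive` switch exists for users who prefer closed thresholds).
2. **Pair restriction.** Keep SNP pairs with at least one partner in that
   set (`restrictPairsToSnpSet()`).
3. **Graph construction** at pair significance $\alpha = 0.05$ (strict).
4. **Display threshold** $\tau$: `filterEdgesByWeight()` hides edges with
   $w < \tau$ (default 50). This thins the *display only*: nodes, colored
   status and the downstream analysis SNP set are computed on the
   unfiltered graph. A documented flag (`viewFromTauGraph`) derives the
   genotype-view SNP set from the τ-surviving edges instead, for users who
   want the two views strictly linked.

# SNP-to-gene assignment

A SNP inside a locus (1-based inclusive coordinates) is assigned at
distance 0; otherwise the same-chromosome gene minimizing
$\min(|pos-start|, |pos-end|)$ wins. Policies the mapping needs but that
no convention fixes are declared, deterministic and logged:

* equal distance to two genes → the gene with the smaller start;
* a SNP inside two overlapping loci → the smaller-span (more specific)
  locus, ties again by smaller start;
* cross-chromosome assignment is never made; pairs containing an
  unassigned SNP are dropped from graph construction and counted;
* no maximum distance by default (`maxDist` is available).

Note the boundary distance is the coordinate difference, not the gap
length: a SNP at position 250 and a locus starting at 400 are 150 apart.

# Cohort genotype summaries

Calls are *simplified* against the reference base by counting
non-reference alleles: 0 → REF, 1 → HET, 2 → HOM (two different
non-reference alleles still count as HOM). Per SNP and phenotype group the
package reports the raw genotype distribution, the three-state counts, the
*consensus* (majority state) and its *strength* — the fraction of
non-missing patients carrying the consensus state (so the strength is at
least 1/3 when all three states occur, and 1 iff the group is unanimous).
Missing calls are excluded from all counts; a group with only missing
calls has an undefined consensus and strength 0 and is excluded from the
relevance rule. Consensus ties are broken in the fixed order
REF < HET < HOM.

**Relevance rule.** A SNP is flagged *relevant* when the two groups either
disagree in consensus state or agree but differ in consensus strength by at
least δ = 10 percentage points. The threshold is inclusive ("at least"),
computed on exact fractions with a 1e-12 tolerance so that a true
10.000…-point difference is never lost to floating-point rounding.

**Pearson χ² test.** Per SNP, the 2 × c table of group × genotype counts is
tested for independence without continuity correction
(df = c − 1, p from the χ² distribution). Categories default to the raw
allele combinations; a `"state"` switch uses the simplified three states
instead. Tables with fewer than two nonzero categories (or an empty group)
are degenerate and get p = 1 by convention, flagged rather than dropped.
Expected counts below 5 raise a logged caution, not a different test.

**Genotype view.** `buildGenotypeViewModel()` produces one column per SNP:
the −log₁₀ p significance bar (the SNP's best single-locus p over all
traits, with the minimizing trait recorded; p = 0 is clamped at 1e-300,
the Manhattan-plot convention), both group summaries and distributions,
the χ² p, the relevance flag, the reference base and a selected
individual's call. Columns order by genomic position, or alternatively by
the pooled-cohort majority genotype.

# Expression statistics and the mirror scans

Differential expression between the groups uses a two-sample t-test per
gene — Welch by default, since equal group variances are not guaranteed in
case/control cohorts; a pooled-variance switch exists. P-values are
corrected by Benjamini–Hochberg step-up FDR (`bhFdr()`, delegating to
`stats::p.adjust`), and genes rank by p (rank 1 most significant). Heatmaps
draw per-gene centered expression on a symmetric green–red gradient,
columns grouped by phenotype, rows in FDR order, optionally aggregated to
the two group mean profiles.

The package also ships *mirror* scans so a pipeline can be exercised
without external association software: per (SNP, gene) a simple linear
regression of expression on the additive genotype code (non-reference
allele count 0/1/2, missing calls dropped; slope t-test p and R²), and per
(pair, gene) the linear model
`expression ~ codeA + codeB + codeA:codeB`, reporting the
interaction-term p — the two-locus quantitative-trait convention.
Monomorphic SNPs and rank-deficient pairs are flagged with p = 1. These
scans mirror the input format and modeling convention; numerical equality
with any specific external tool is neither claimed nor tested. Their
correctness is established against `lm()` on random instances, and their
calibration on null and additive-only data.

# The synthetic cohort generator

`generateDataset()` draws a complete, self-consistent cohort with known
ground truth, writing the same six tab-separated tables the readers
consume. Defaults emulate a mid-sized case/control eQTL study: 193
affected and 307 unaffected patients, 200 biallelic SNPs tiled across the
loci of 10 genes on one synthetic chromosome, non-reference allele
frequencies uniform on (0.05, 0.5), Hardy–Weinberg genotypes with
independent SNPs, and unit-variance Gaussian expression noise. The
reference allele is defined as the major allele of the combined cohort
(ties alphabetical). Two signal types can be spiked:

* **Two-locus interactions** add `effect × codeA × codeB` to the target
  gene. Spiked SNPs draw allele frequencies from U(0.35, 0.5). This is a
  power-design choice made when the generator was specified: an
  interaction on the product of additive codes also induces marginal
  single-locus signal of magnitude
  $R^2 \approx \mathrm{Var}(a)\,E[b]^2 / \mathrm{Var}(y)$ — about
  0.13–0.17 for common variants at effect 1.0 and noise SD 1.0, safely
  above the cascade's $R^2 > 0.1$ gate, but below 0.01 for minor allele
  frequencies under ~0.2, where the cascade itself would eliminate the
  spiked pair. Rare-variant interactions are underpowered at these study
  sizes and are not what the recovery checks probe.
* **Group-differential SNPs** raise the affected group's non-reference
  allele frequency by `shift`. Their baseline frequency is drawn from
  U(0.05, 0.45 − shift), again by design: a +shift starting below the
  heterozygote-consensus band expresses either as a REF→HET consensus
  change or as a strength drop of roughly 2·shift, whereas a shift
  applied inside that band (e.g. 0.4 → 0.6) leaves consensus state *and*
  strength nearly unchanged (both give HET at strength 0.48) and would
  make the manifest's "relevant" label meaningless. Shifts that would push
  a frequency outside [0, 1] are an error.

What the generator deliberately does **not** emulate: linkage
disequilibrium (SNPs are independent), population structure and
relatedness, covariates, missing genotype calls, and more than two
phenotype groups. Passing recovery checks on these cohorts therefore
demonstrates the correctness and calibration of the cascade's logic, not
robustness to the correlation structure of real genotype panels.

# Numerical and design choices

* All significance thresholds are strict (`<`, `>`), as is conventional
  for "p < 0.05"-style filters; inclusive variants are switchable.
* Degenerate statistics are conventions, not errors: χ² on a
  single-category table gives p = 1 (flagged); a t-test on constant equal
  data gives t = 0, p = 1; a monomorphic SNP scans at p = 1, R² = 0.
* Exact regression fits (zero residual) report p = 0 / R² = 1 rather than
  dividing by zero.
* File output uses fixed `%.17g` formatting, so scan → file → parse
  round-trips reproduce p-values bit-exactly and rerunning a workflow is
  byte-identical.
* Renderings are deterministic functions of their inputs: the network
  layout is a seeded force-directed embedding, and the SVG writer emits
  canonical text (fixed 2-decimal coordinates, no timestamps). Node
  palette: ten distinguishable hues, cycled with a warning beyond ten
  colored genes — roughly the practical limit for categorical color.
* Genotype view gray-scale: REF = white, HET = 50% gray, HOM = black;
  heterozygous calls draw split two-color fills in place of hatching.

# Problem sizes used by the checks

The test suite establishes the graph construction against a brute-force
triple count on hundreds of random instances (up to 200 pairs, 10 genes),
the χ² and regression paths against `chisq.test()` and `lm()`, and the
end-to-end cascade on 50 seeded replicates of the default cohort (500
patients, 200 SNPs, 10 genes, 3 spiked interactions, 10 group-differential
SNPs, ~300 scanned candidate pairs per replicate) — sizes chosen so the
full suite completes in a couple of minutes on one CPU while keeping the
binomial error of the recovery rates small. `scripts/acceptance.R` runs
one such study end to end at a user-supplied seed and reports the cascade
counts and recovery rates it computes.

# Known limitations

* Only two phenotype groups are supported throughout.
* Nearest-gene assignment is transcript-unaware and strand-unaware.
* No permutation p-values, covariate adjustment, or case/control
  (logistic) trait models in the scans.
* The file dialects cover header-keyed tab-separated layouts; binary or
  VCF/PED inputs are out of scope.
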