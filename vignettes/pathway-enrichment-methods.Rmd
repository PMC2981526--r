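---
title: "Pathway enrichment of GWAS signals by SNP resampling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway enrichment of GWAS signals by SNP resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aligator)
```

## The problem

A genome-wide association study (GWAS) tests hundreds of thousands of
SNPs for allele-frequency differences between cases and controls. Only a
handful of SNPs usually reach genome-wide significance, yet much of the
heritable signal hides below that threshold. If the sub-threshold signal
is real, it should concentrate in genes that work together — in pathways
— rather than scatter uniformly. `aligator` tests exactly that: whether
functional categories of genes (GO, KEGG, mouse-phenotype or custom
sets) contain more nominally associated genes than chance allows.

Two features of GWAS data make the obvious test (a hypergeometric /
Fisher test of the overlap between "significant genes" and a category)
wrong:

1. **Gene size.** Genes carry wildly different numbers of SNPs. A gene
   with 150 SNPs has many more chances to contain a nominally significant
   SNP than a gene with 3, so under the null the significant-gene list is
   *not* a uniform draw from all genes. A category of large genes will
   look "enriched" with no biology at all.
2. **Linkage disequilibrium (LD).** Nearby SNPs are correlated, and
   neighbouring or overlapping genes can share the very same SNPs, so one
   association signal can masquerade as several "independent" genes.

## The resampling engine

The engine converts a list of significant SNPs into a list of significant
genes and compares each category's hit count against *replicate gene
lists* built by random SNP sampling:

1. **SNP-to-gene assignment.** A SNP is assigned to every gene whose body
   (plus a symmetric window, default 20 kb, closed bounds) contains it.
   Unassigned SNPs stay in the sampling frame.
2. **Significant gene list.** A gene is listed when at least one of its
   SNPs has association p strictly below `alphaGene` (default 0.001).
   Each gene counts once no matter how many significant SNPs it holds.
3. **Replicate lists.** SNPs (not genes) are drawn uniformly without
   replacement; each drawn SNP contributes all its genes not already on
   the list, until the list reaches exactly the observed list's length.
   Because the draw is over SNPs, a gene's chance of entering a null list
   is proportional to its SNP content — this is the gene-size correction.
   When the last drawn SNP would overshoot the target length, its genes
   are added in random order and truncated; the original scheme leaves
   this case unstated, and exact-length lists are the simplest contract.
4. **Hit counting.** Within a category, one SNP may support at most one
   gene: the count is the size of a maximum bipartite matching between
   listed member genes and their defining SNPs (solved with igraph when
   SNPs are shared; trivially the gene count otherwise). Replicate-list
   genes carry the single SNP that sampled them, so the same rule applies
   to the null. Two overlapping genes defined by one shared SNP count
   once — the CR1/CR2 situation.
5. **P-values.** All resampling p-values use the add-one convention
   (r + 1)/(n + 1), bounded below by 1/(n + 1). The *study-wide* p-value
   of a category asks how often a replicate list would produce at least
   one category anywhere in the collection as extreme as the observed one
   (leave-one-out over the replicate lists). Categories whose significant
   -gene sets are identical are collapsed to the single most significant
   row (ties: smallest set id); empty hit sets are never collapsed, since
   there is nothing shared to deduplicate. The *excess of enriched
   categories* test compares the number of enriched categories (p below a
   threshold, at least two signals, after deduplication) with each
   replicate's own count under identical rules.
6. **Region exclusion and signal clusters.** Genes overlapping a region
   dominated by long-range LD with one very strong locus can be removed
   wholesale while keeping the presumed causal gene (`excludeRegion`,
   the APOE treatment), and clusters of genes known to tag one signal can
   be collapsed to a single representative (`collapseLdClusters`).

### Cross-study replication and joint enrichment

Replication restricts attention to the categories enriched in a discovery
study (p < 0.05 with ≥ 2 signals) and counts how many are also enriched
in a second study. The null for that count reuses the replication study's
replicate lists *over the same selected categories*, which keeps the
correlation between overlapping categories — a Binomial(#selected, 0.05)
tail would ignore it. Only the replication study's replicates are
resampled; re-running the discovery study as well would answer a
different question (joint discovery), not replication of a fixed
selection. Joint enrichment of a category is the product of its two
enrichment p-values; its multiplicity-corrected p compares the observed
product with each paired replicate's *minimum* product over all
categories tested in both studies. For a single category and independent
uniform p-values the product's null CDF is the closed form
P(U₁U₂ ≤ x) = x(1 − ln x), which the tests verify by simulation.

### Gene-level validation tests

Three individual-genotype tests validate enrichment findings:

* **Gene-wide corrected minimum p** — the best single-SNP allelic
  chi-squared p in a gene, with significance from permuting disease
  status among individuals (preserving LD); 1000 permutations, escalating
  to 10,000 when the first-stage p < 0.01; genes without any SNP at
  p < 0.05 are screened out.
* **Set-based average chi-squared** — the mean 1-df allelic chi-squared
  over a SNP set, same permutation null; robust to LD within and between
  genes and to shared SNPs.
* **GSEA** — genes ranked by decreasing −log Simes p (the Simes gene-wide
  p-value min_i m·p₍ᵢ₎/i absorbs gene size); the enrichment score is the
  maximum of a weighted running sum (in-set steps proportional to the
  gene score, weight exponent 1 — the simplest member of the weighted
  family, fixed here as a documented constant). Two null modes are
  provided because one study may have summary statistics only:
  `genotype` permutes phenotypes and recomputes every gene statistic;
  `summary` permutes gene labels. Both are exposed and labelled in the
  output rather than guessing which a given published analysis used; on
  independent, equally sized genes they agree (checked by a paired
  simulation), while under strong LD or very unequal gene sizes the
  genotype mode is the defensible one.

The allelic chi-squared is the classical 1-df test on the 2×2 table of
allele counts (two per individual) with no continuity correction;
missing dosages are dropped per SNP; monomorphic SNPs are flagged and
given p = 1. Permutation draws are anchored to the sorted individual
ids, so storing the same individuals in a different row order cannot
change a permutation p-value at a fixed seed.

### Effective number of independent tests

For the "more significant SNPs than expected" table, the number of
independent SNPs is estimated with a sliding-window form: ordered by
position, SNP i contributes √(1 − max r²) over its preceding
`windowSnps` (default 50) neighbours. This reproduces the limits that
matter — independent SNPs count fully (Keff = M), perfectly correlated
ones count once (Keff = 1) — while staying transparent; pairs absent
from the LD table count as independent, with a warning. The expected
number of significant SNPs at level α is then Keff·α, the observed
effective count is compared with a Binomial(round(Keff), α) upper tail
(exact summation; a non-integer observed count is ceiled, which is
conservative), and the estimated/expected ratio is reported to two
decimals.

## The synthetic-data generator

No genotypes are distributed with the studies this methodology targets,
so the package ships a generator that emulates the structural features
the engine must survive:

* **Block LD** via a latent first-order autoregressive Gaussian per gene
  block (parameter `ldRho`, default 0.8), thresholded at qnorm(MAF) on
  two independent haplotypes per individual. This gives Hardy–Weinberg
  genotypes and a closed-form adjacent-SNP correlation that the tests
  verify by numeric integration — the reason this model was chosen over
  haplotype copying.
* **Highly variable gene size**: per-gene SNP counts uniform on
  [2, 25] by default, over 200 genes on one synthetic chromosome with
  50 kb bodies and 50 kb gaps (wider than twice the 20 kb window, so
  only deliberately overlapping genes share SNPs).
* **Shared SNPs across adjacent genes** (`overlapFrac`): a fraction of
  consecutive genes overlap the previous gene's tail, so boundary SNPs
  fall in both bodies — the overlapping-paralog and HLA situations.
* **Planted association**: in nominated sets, half the genes (default
  `causalFraction = 0.5`) carry one causal SNP with per-allele odds
  ratio `causalOr`; disease status follows a logistic model with
  baseline prevalence 0.1 (an arbitrary but fixed population value),
  log-odds centred at the expected causal dosage so the realised
  prevalence stays near baseline; cases and controls are collected by
  rejection from the population simulator, preserving the retrospective
  design the allelic test assumes, with an error after a bounded number
  of draws if the quota is unreachable.

What the generator does *not* emulate: realistic human LD maps and
recombination hotspots, imputation uncertainty, population
stratification, X-chromosome inheritance, and genotyping artefacts.
Passing calibration and recovery tests on these data therefore shows the
engine's statistics are correct under controlled LD and gene-size
heterogeneity, not that any particular real-data finding is right.

## Problem sizes used by the test suite and acceptance script

All sizes below are the package's own choices, documented so the numbers
are interpretable:

* **Null calibration**: a fixed structure of 600 genes and 200
  categories of 60 genes; 200 independent null runs (100 in the
  acceptance script) with uniform SNP p-values, gene lists at SNP
  p < 0.05, and 1000 replicate lists per run. Categories of this size
  keep null hit counts large enough that the discrete add-one
  permutation p approaches its nominal level; with very small categories
  the test is valid but conservative (attainable levels fall below
  0.05), which is a property of any discrete permutation test rather
  than a defect of the engine.
* **Gene-size bias**: 200 genes, one category of the 10 largest; 500
  null runs (200 in the script) with 400 replicate lists each, gene
  lists at SNP p < 0.01.
* **Recovery**: paired studies of 2000 cases + 2000 controls, 200 genes
  with 2–10 SNPs each, 50 sets of 10 genes, 5 planted sets at odds
  ratio 1.5; 20 seeds in the test suite, 8 in the acceptance script.
* **Permutation-test checks** run at 300–800 individuals with 1000–2000
  permutations, against closed forms (Šidák for independent SNPs, the
  asymptotic chi-squared tail for single-SNP sets) within Monte-Carlo
  tolerance.

## Numerical and interface choices

* Internal coordinates are 1-based inclusive; BED input is converted at
  the boundary; a leading `chr` is stripped from chromosome names.
* The assignment window uses closed bounds at exactly `windowBp`
  ("within 20 kb" read inclusively) and gene-list membership uses strict
  p < alpha; both boundaries are tested explicitly.
* Region exclusion removes genes with any base of overlap —
  conservative, since partial overlap is enough for LD contamination.
* Replicate generation and replicate hit counting are implemented in
  C++ (Rcpp) but draw from R's RNG, so `set.seed` makes every analysis
  reproducible regardless of platform; one seed governs a run and each
  replicate's draws derive from the single stream in replicate order.
* Zero p-values cannot occur: add-one conventions bound permutation
  p-values away from 0, and underflowing chi-squared tails are clamped
  to the smallest positive double.
* `runPipeline` drives the stages from a flat key = value config file in
  which unknown keys are errors (a misspelled threshold must not
  silently fall back to a default), writes every table as a
  `#`-headed TSV, and leaves exactly one `manifest.json` (config
  snapshot, seed, input digests, package version, timing) per output
  directory. The exported functions are the package's interface; a thin
  command-line wrapper over `runPipeline` ships in `inst/scripts/`.

## Known limitations

* The effective-tests estimator is a transparent sliding-window bound,
  not a full multivariate correction; with pathological LD patterns it
  can under- or over-count relative to an exact eigenvalue method.
* Enrichment p-values inherit the discreteness of small hit counts:
  for categories with few mappable genes the attainable significance
  levels are coarse, and the excess-of-enriched-categories p is
  correspondingly conservative in the far tail.
* The replication overlap null conditions on the discovery selection;
  it does not model uncertainty in which categories were selected.
* Gene-level tests require individual genotypes; for summary-only
  studies only the `summary` GSEA mode and the resampling engine apply.
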