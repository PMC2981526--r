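test_that("Simes p matches direct evaluation and its envelope", {
  expect_equal(simesP(0.2), 0.2)
  expect_equal(simesP(c(0.01, 0.04, 0.9)), 0.03)  # min(0.03, 0.06, 0.9)
  expect_equal(simesP(rep(0.3, 7)), 0.3)          # all equal: unchanged
  expect_error(simesP(numeric(0)), "at least one")
  expect_error(simesP(c(0.5, 0)), "0, 1")
  set.seed(14)
  for (i in 1:50) {
    ps <- runif(sample(1:8, 1))
    m <- length(ps)
    s <- simesP(ps)
    exhaustive <- min(m * sort(ps) / seq_len(m))
    expect_equal(s, exhaustive)
    expect_gte(s, min(ps))
    expect_lte(s, m * min(ps))
    expect_lte(s, 1)
  }
})

## one null dataset reused by the permutation tests below
null_sim <- local({
  cfg <- simulationConfig(nCases = 400, nControls = 400, nGenes = 12,
                          snpsPerGene = c(10, 10), ldRho = 0,
                          mafRange = c(0.3, 0.3), nSets = 0, seed = 71)
  simulateDataset(cfg)
})

test_that("single-SNP gene: corrected min-p agrees with the raw p-value", {
  ss <- computeSummaryStats(null_sim$dataset)
  ## a mildly associated SNP, where the asymptotic tail is accurate
  snp <- ss$snp_id[which.min(abs(ss$p_value - 0.03))]
  res <- geneMinpCorrected(null_sim$dataset, snp, nPermBase = 1000, seed = 5)
  expect_true(res$analysed)
  expect_gte(res$corrected_min_p, res$best_p)
  se <- sqrt(res$best_p * (1 - res$best_p) / res$n_perm_used)
  expect_lt(abs(res$corrected_min_p - res$best_p), 3 * se + 0.01)
})

test_that("independent null SNPs: corrected min-p near the Sidak value", {
  ss <- computeSummaryStats(null_sim$dataset)
  ## pick a 10-SNP gene whose best p passes the screen
  gene_snps <- split(ss$snp_id, rep(1:12, each = 10))
  best <- vapply(gene_snps, function(s) min(ss$p_value[match(s, ss$snp_id)]), 0)
  g <- which(best < 0.05)[1]
  expect_false(is.na(g))
  res <- geneMinpCorrected(null_sim$dataset, gene_snps[[g]],
                           nPermBase = 1000, seed = 6)
  sidak <- 1 - (1 - res$best_p)^10
  se <- sqrt(sidak * (1 - sidak) / res$n_perm_used)
  expect_lt(abs(res$corrected_min_p - sidak), 3 * se + 0.02)
  ## permutation count escalates only below 0.01
  expect_true(res$n_perm_used %in% c(1000L, 10000L))
})

test_that("gene screen excludes genes without a SNP at p < 0.05", {
  ## dosages alternate with phenotype: identical case and control counts
  ds <- make_dataset(cbind(rep(c(0L, 1L), 50)),
                     rep(c("case", "case", "control", "control"), 25))
  res <- geneMinpCorrected(ds, "rs001")
  expect_false(res$analysed)
  expect_true(is.na(res$corrected_min_p))
})

test_that("permutation tests are invariant to individual storage order", {
  ds <- null_sim$dataset
  set.seed(33)
  perm <- sample(nrow(dosages(ds)))
  dsp <- new("GenotypeDataset", dosages = dosages(ds)[perm, , drop = FALSE],
             phenotype = phenotype(ds)[perm],
             individualIds = ds@individualIds[perm], snpInfo = snpInfo(ds))
  snps <- snpInfo(ds)$snp_id[1:10]
  expect_identical(setAverageChi2P(ds, snps, nPerm = 300, seed = 11),
                   setAverageChi2P(dsp, snps, nPerm = 300, seed = 11))
  expect_identical(geneMinpCorrected(ds, snps, nPermBase = 300, seed = 11),
                   geneMinpCorrected(dsp, snps, nPermBase = 300, seed = 11))
})

test_that("set-based average chi-squared is calibrated and powered", {
  ## single-SNP set at large n: permutation p close to the analytic tail
  ss <- computeSummaryStats(null_sim$dataset)
  i1 <- which.min(abs(ss$p_value - 0.2))
  snp1 <- ss$snp_id[i1]
  p_perm <- setAverageChi2P(null_sim$dataset, snp1, nPerm = 2000, seed = 3)
  p_asym <- ss$p_value[i1]
  expect_lt(abs(p_perm - p_asym), 0.02 + 3 * sqrt(p_asym * (1 - p_asym) / 2000))

  ## null calibration: disjoint 10-SNP sets across seeds
  set.seed(8)
  ps <- unlist(lapply(1:4, function(seed) {
    cfg <- simulationConfig(nCases = 250, nControls = 250, nGenes = 30,
                            snpsPerGene = c(10, 10), nSets = 0, seed = 80 + seed)
    sim <- simulateDataset(cfg)
    ids <- snpInfo(sim$dataset)$snp_id
    vapply(split(ids, rep(1:30, each = 10)), function(s)
      setAverageChi2P(sim$dataset, s, nPerm = 500, seed = seed), 0)
  }))
  expect_gte(mean(ps < 0.05), 0.02)
  expect_lte(mean(ps < 0.05), 0.08)

  ## planted signal is detected
  cfgp <- simulationConfig(nCases = 1000, nControls = 1000, nGenes = 10,
                           snpsPerGene = c(5, 5), nSets = 2, genesPerSet = 5,
                           plantedSets = "SET01", causalOr = 1.5,
                           causalFraction = 0.6, seed = 44)
  simp <- simulateDataset(cfgp)
  map <- mapSnpsToGenes(computeSummaryStats(simp$dataset), simp$genes)
  set_snps <- unique(unlist(geneToSnps(map)[
    geneSets(simp$sets)$SET01], use.names = FALSE))
  expect_lt(setAverageChi2P(simp$dataset, set_snps, nPerm = 500, seed = 2),
            0.05)
  expect_error(setAverageChi2P(
    make_dataset(cbind(rep(0L, 20)), rep(c("case", "control"), 10)), "rs001"),
    "monomorphic")
})

test_that("GSEA score is maximal for the top-ranked set, by enumeration", {
  scores <- stats::setNames(sort(runif(10, 0.5, 3), decreasing = TRUE),
                            sprintf("g%d", 1:10))
  top3 <- gseaEnrichmentScore(scores, c(rep(TRUE, 3), rep(FALSE, 7)))
  for (sub in utils::combn(10, 3, simplify = FALSE)) {
    inset <- seq_len(10) %in% sub
    expect_lte(gseaEnrichmentScore(scores, inset), top3 + 1e-12)
  }
})

test_that("GSEA ranks planted sets and handles degenerate inputs", {
  ## equal statistics: every permutation ties, p = 1
  stats_eq <- stats::setNames(rep(0.5, 30), sprintf("g%d", 1:30))
  sets <- make_sets(list(S1 = sprintf("g%d", 1:5),
                         S2 = sprintf("g%d", 26:30)))
  res_eq <- gsea(stats_eq, sets, nPerm = 100, mode = "summary", seed = 1)
  expect_true(all(res_eq$empirical_p == 1))

  ## a set of the most significant genes is detected
  set.seed(10)
  gs <- stats::setNames(runif(30), sprintf("g%d", 1:30))
  gs[1:5] <- gs[1:5] / 5000
  res <- gsea(gs, sets, nPerm = 400, mode = "summary", seed = 2)
  expect_lt(res$empirical_p[res$set_id == "S1"], 0.05)
  expect_gt(res$empirical_p[res$set_id == "S2"], 0.05)

  ## sets without enough scored genes are skipped with a warning
  sets2 <- make_sets(list(S1 = sprintf("g%d", 1:5), EMPTY = c("zz1", "zz2", "zz3")))
  expect_warning(res2 <- gsea(gs, sets2, nPerm = 50, mode = "summary"),
                 "skipped")
  expect_equal(res2$set_id, "S1")
})

test_that("genotype-mode and summary-mode GSEA agree on independent null data", {
  cfg <- simulationConfig(nCases = 300, nControls = 300, nGenes = 40,
                          snpsPerGene = c(3, 3), ldRho = 0, nSets = 15,
                          genesPerSet = 8, seed = 55)
  sim <- simulateDataset(cfg)
  ss <- computeSummaryStats(sim$dataset)
  map <- mapSnpsToGenes(ss, sim$genes)
  gstats <- geneSimesStats(ss, map)
  r_sum <- gsea(gstats, sim$sets, nPerm = 200, mode = "summary", seed = 4)
  r_gen <- gsea(gstats, sim$sets, nPerm = 200, mode = "genotype",
                dataset = sim$dataset, map = map, seed = 4)
  expect_equal(r_sum$set_id, r_gen$set_id)
  expect_equal(r_sum$es, r_gen$es)   # observed scores identical
  ks <- suppressWarnings(stats::ks.test(r_sum$empirical_p, r_gen$empirical_p))
  expect_gt(ks$p.value, 0.01)
})
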