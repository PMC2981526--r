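test_that("allelic chi-squared matches the hand-computed 2x2 value", {
  ## cases: 20 people, 30 minor / 10 major alleles; controls: 20 people,
  ## 20 / 20. chi2 = n(ad-bc)^2 / row-col products = 16/3
  case_dos <- c(rep(2, 10), rep(1, 10))
  ctrl_dos <- rep(1, 20)
  ds <- make_dataset(cbind(c(case_dos, ctrl_dos)),
                     c(rep("case", 20), rep("control", 20)))
  ss <- computeSummaryStats(ds)
  expect_equal(ss$chi2, 16 / 3, tolerance = 1e-12)
  expect_equal(ss$p_value, pchisq(16 / 3, 1, lower.tail = FALSE))

  ## identical case/control allele counts: chi2 = 0, p = 1
  ds0 <- make_dataset(cbind(c(case_dos, case_dos)),
                      c(rep("case", 20), rep("control", 20)))
  expect_equal(computeSummaryStats(ds0)$chi2, 0)
  expect_equal(computeSummaryStats(ds0)$p_value, 1)

  ## monomorphic SNP is flagged with p = 1
  dsm <- make_dataset(cbind(rep(0L, 10), c(rep(1L, 5), rep(0L, 5))),
                      rep(c("case", "control"), 5))
  ssm <- computeSummaryStats(dsm)
  expect_true(ssm$monomorphic[1] && !ssm$monomorphic[2])
  expect_equal(ssm$p_value[1], 1)

  ## permuting individual order leaves all statistics unchanged
  set.seed(1)
  perm <- sample(nrow(dosages(ds)))
  dsp <- new("GenotypeDataset", dosages = dosages(ds)[perm, , drop = FALSE],
             phenotype = phenotype(ds)[perm],
             individualIds = ds@individualIds[perm], snpInfo = snpInfo(ds))
  expect_equal(computeSummaryStats(dsp)$chi2, ss$chi2)
})

test_that("simulation is deterministic and truth is empty under the null", {
  cfg <- simulationConfig(nCases = 60, nControls = 60, nGenes = 10,
                          nSets = 4, genesPerSet = 3, seed = 123)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(dosages(a$dataset), dosages(b$dataset))
  expect_identical(a$genes, b$genes)
  expect_identical(geneSets(a$sets), geneSets(b$sets))
  expect_length(a$truth$causal_snp_ids, 0L)      # causalOr = 1: null
  expect_true(all(a$truth$snp_or == 1))
})

test_that("null p-values are uniform (KS, independent SNPs, 5 seeds)", {
  ps <- unlist(lapply(1:5, function(seed) {
    cfg <- simulationConfig(nCases = 250, nControls = 250, nGenes = 30,
                            snpsPerGene = c(5, 5), ldRho = 0,
                            mafRange = c(0.2, 0.5), nSets = 0, seed = seed)
    computeSummaryStats(simulateDataset(cfg)$dataset)$p_value
  }))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("null calibration: fraction of p < 0.05 near nominal over seeds", {
  ps <- unlist(lapply(1:13, function(seed) {
    cfg <- simulationConfig(nCases = 150, nControls = 150, seed = seed,
                            nGenes = 60)
    computeSummaryStats(simulateDataset(cfg)$dataset)$p_value
  }))
  expect_gte(length(ps), 10000)
  expect_gte(mean(ps < 0.05), 0.04)
  expect_lte(mean(ps < 0.05), 0.06)
})

test_that("ldRho = 0 gives uncorrelated genotypes at n = 2000", {
  cfg <- simulationConfig(nCases = 1000, nControls = 1000, nGenes = 1,
                          snpsPerGene = c(10, 10), ldRho = 0, nSets = 0,
                          seed = 31)
  d <- dosages(simulateDataset(cfg)$dataset)
  cm <- cor(d)
  expect_lt(mean(abs(cm[lower.tri(cm)])), 0.05)
})

test_that("ldRho = 0.9 matches the latent-threshold correlation oracle", {
  ## closed form by numeric integration: alleles are indicators of a
  ## bivariate normal with correlation rho below qnorm(maf); the dosage
  ## correlation equals the allele correlation (two independent haplotypes)
  rho <- 0.9; maf <- 0.3
  t <- qnorm(maf)
  p11 <- integrate(function(z)
    dnorm(z) * pnorm((t - rho * z) / sqrt(1 - rho^2)), -Inf, t)$value
  target <- (p11 - maf^2) / (maf * (1 - maf))
  cfg <- simulationConfig(nCases = 2000, nControls = 2000, nGenes = 1,
                          snpsPerGene = c(12, 12), ldRho = rho,
                          mafRange = c(maf, maf), nSets = 0, seed = 57)
  d <- dosages(simulateDataset(cfg)$dataset)
  adj <- vapply(1:(ncol(d) - 1), function(j) cor(d[, j], d[, j + 1]), 0)
  expect_lt(abs(mean(adj) - target), 0.1)
})

test_that("planted effects make causal SNPs more significant, every seed", {
  for (seed in 1:5) {
    cfg <- simulationConfig(nCases = 2000, nControls = 2000, nGenes = 40,
                            snpsPerGene = c(2, 10), nSets = 8,
                            genesPerSet = 6,
                            plantedSets = c("SET01", "SET02"),
                            causalOr = 1.5, causalFraction = 0.5,
                            seed = seed)
    sim <- simulateDataset(cfg)
    ss <- computeSummaryStats(sim$dataset)
    causal <- ss$snp_id %in% sim$truth$causal_snp_ids
    expect_gt(length(sim$truth$causal_snp_ids), 0)
    expect_lt(median(ss$p_value[causal]), median(ss$p_value[!causal]))
  }
})

test_that("overlapping gene layout shares boundary SNPs between genes", {
  cfg <- simulationConfig(nCases = 30, nControls = 30, nGenes = 20,
                          overlapFrac = 0.5, nSets = 0, seed = 9)
  sim <- simulateDataset(cfg)
  map <- mapSnpsToGenes(
    cbind(snpInfo(sim$dataset), p_value = 0.5), sim$genes, windowBp = 0)
  expect_gt(sum(lengths(snpToGenes(map)) > 1L), 0)
})

test_that("unreachable case quota raises a bounded-draw error", {
  cfg <- simulationConfig(nCases = 500, nControls = 5, nGenes = 2,
                          nSets = 0, prevalence = 0.001, seed = 2)
  expect_error(simulateDataset(cfg), "could not reach")
})
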