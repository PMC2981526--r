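test_that("replicate lists have exact length, no duplicates, determinism", {
  map <- toy_map()
  r1 <- generateReplicateLists(map, targetLength = 2, nReplicates = 50,
                               seed = 4)
  expect_true(all(lengths(replicateLists(r1)) == 2L))
  expect_true(all(vapply(replicateLists(r1),
                         function(l) !anyDuplicated(l), NA)))
  r2 <- generateReplicateLists(map, targetLength = 2, nReplicates = 50,
                               seed = 4)
  expect_identical(replicateLists(r1), replicateLists(r2))
  expect_identical(r1@definingSnps, r2@definingSnps)

  ## one-gene-per-SNP map: the list is the first target distinct genes
  map1 <- new("SnpGeneMap", windowBp = 0,
              snpToGenes = list(a = "G1", b = "G2", c = "G3", d = "G4"),
              geneToSnps = list(G1 = "a", G2 = "b", G3 = "c", G4 = "d"))
  r3 <- generateReplicateLists(map1, targetLength = 3, nReplicates = 20,
                               seed = 1)
  expect_true(all(lengths(replicateLists(r3)) == 3L))
  expect_error(generateReplicateLists(map1, targetLength = 5,
                                      nReplicates = 1, seed = 1),
               "exceeds")
})

test_that("a two-gene SNP contributes either gene uniformly at target 1", {
  map <- new("SnpGeneMap", windowBp = 0,
             snpToGenes = list(s = c("GA", "GB")),
             geneToSnps = list(GA = "s", GB = "s"))
  r <- generateReplicateLists(map, targetLength = 1, nReplicates = 1000,
                              seed = 99)
  frac_a <- mean(vapply(replicateLists(r), `[[`, "", 1L) == "GA")
  expect_gt(frac_a, 0.45)
  expect_lt(frac_a, 0.55)
})

test_that("one-SNP-one-gene hit counting equals maximum matching", {
  ## disjoint defining SNPs: both genes count
  l2 <- make_sig_list(list(A = "s1", B = "s2"))
  expect_equal(countCategoryHits(l2, c("A", "B")), 2L)
  ## a single shared SNP: the two genes are one signal
  l1 <- make_sig_list(list(CR1 = "s1", CR2 = "s1"))
  expect_equal(countCategoryHits(l1, c("CR1", "CR2")), 1L)
  ## gene outside the category does not count
  expect_equal(countCategoryHits(l2, "A"), 1L)
  expect_equal(countCategoryHits(l2, "Z"), 0L)
  ## partial sharing: 3 genes, 2 SNPs
  l3 <- make_sig_list(list(A = "s1", B = c("s1", "s2"), C = "s2"))
  expect_equal(countCategoryHits(l3, c("A", "B", "C")),
               brute_matching(list(A = "s1", B = c("s1", "s2"), C = "s2")))

  ## random instances against the brute-force matching oracle
  set.seed(21)
  for (i in 1:60) {
    n_g <- sample(2:4, 1); n_s <- sample(2:4, 1)
    def <- lapply(seq_len(n_g), function(j)
      sample(sprintf("s%d", 1:n_s), sample(n_s, 1)))
    names(def) <- sprintf("G%d", seq_len(n_g))
    lst <- make_sig_list(def)
    expect_equal(countCategoryHits(lst, names(def)), brute_matching(def))
  }

  ## duplicating a gene's significant SNPs never changes the count
  ldup <- make_sig_list(list(A = c("s1", "s3", "s4"), B = "s2"))
  expect_equal(countCategoryHits(ldup, c("A", "B")), 2L)
})

test_that("enrichment p matches exhaustive enumeration on a tiny instance", {
  map <- toy_map()   # s1->A; s2->A,B; s3->B; s4->C; s5 unmapped
  B <- 4000
  reps <- generateReplicateLists(map, targetLength = 2, nReplicates = B,
                                 seed = 12)
  sets <- make_sets(list(AB = c("A", "B"), C = "C"))
  H <- replicateHitMatrix(reps, sets)
  exact2 <- exact_tail(snpToGenes(map), 2, c("A", "B"), 2)
  e <- categoryEnrichmentP(2L, H[, "AB"])
  expected_p <- (1 + B * exact2) / (B + 1)
  mc_se <- sqrt(exact2 * (1 - exact2) / B)
  expect_lt(abs(e$p_enrich - expected_p), 3 * mc_se + 2 / B)
  ## and for the singleton category at hits >= 1
  exact1 <- exact_tail(snpToGenes(map), 2, "C", 1)
  e1 <- categoryEnrichmentP(1L, H[, "C"])
  mc_se1 <- sqrt(exact1 * (1 - exact1) / B)
  expect_lt(abs(e1$p_enrich - (1 + B * exact1) / (B + 1)), 3 * mc_se1 + 2 / B)
})

test_that("enrichment p respects its floor, ceiling and monotonicity", {
  rep_hits <- c(0L, 1L, 2L, 0L, 3L)
  expect_equal(categoryEnrichmentP(0L, rep_hits)$p_enrich, 1)
  expect_equal(categoryEnrichmentP(4L, rep_hits)$p_enrich, 1 / 6)
  ps <- vapply(0:4, function(k) categoryEnrichmentP(k, rep_hits)$p_enrich, 0)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps >= 1 / 6))
  expect_equal(categoryEnrichmentP(2L, rep_hits)$expected, mean(rep_hits))
})

test_that("study-wide p reduces to the category p for a single category", {
  map <- toy_map()
  reps <- generateReplicateLists(map, targetLength = 2, nReplicates = 500,
                                 seed = 3)
  sets <- make_sets(list(AB = c("A", "B")))
  H <- replicateHitMatrix(reps, sets)
  repP <- leaveOneOutP(H)
  e <- categoryEnrichmentP(2L, H[, 1])
  sw <- studywideP(e$p_enrich, repP)
  expect_lte(abs(sw - e$p_enrich), 2 / 501)
  ## extremes of the convention
  expect_equal(studywideP(1, repP), 1)
  expect_equal(studywideP(0, repP), 1 / 501)
  ## multiplicity can only cost
  sets2 <- make_sets(list(AB = c("A", "B"), C = "C", AC = c("A", "C")))
  H2 <- replicateHitMatrix(reps, sets2)
  repP2 <- leaveOneOutP(H2)
  for (c in 1:3) {
    e2 <- categoryEnrichmentP(1L, H2[, c])
    expect_gte(studywideP(e2$p_enrich, repP2), e2$p_enrich - 2 / 501)
  }
})

test_that("identical significant-gene sets deduplicate to the best row", {
  rows <- data.frame(set_id = c("S1", "S2", "S3", "S4"),
                     p_enrich = c(0.04, 0.01, 0.20, 0.01),
                     stringsAsFactors = FALSE)
  hits <- list(S1 = c("A", "B"), S2 = c("B", "A"), S3 = "C",
               S4 = character(0))
  out <- dedupIdenticalCategories(rows, hits)
  expect_setequal(out$set_id, c("S2", "S3", "S4"))
  ## disjoint hit sets unchanged
  out2 <- dedupIdenticalCategories(rows[c(2, 3), ], hits[c("S2", "S3")])
  expect_equal(nrow(out2), 2L)
  ## three-way tie on p: lexicographically smallest id kept
  rows3 <- data.frame(set_id = c("S9", "S2", "S5"),
                      p_enrich = rep(0.02, 3), stringsAsFactors = FALSE)
  hits3 <- list(S9 = "G", S2 = "G", S5 = "G")
  expect_equal(dedupIdenticalCategories(rows3, hits3)$set_id, "S2")
  ## empty hit sets are never collapsed together
  rows0 <- data.frame(set_id = c("E1", "E2"), p_enrich = c(0.9, 0.8),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(dedupIdenticalCategories(
    rows0, list(E1 = character(0), E2 = character(0)))), 2L)
})

test_that("excess summary handles zero enriched categories", {
  map <- toy_map()
  snps <- snp_table(sprintf("s%d", 1:5), (1:5) * 1000,
                    c(0.9, 0.8, 0.7, 0.6, 0.5))
  genes <- gene_table(c("A", "B", "C"), c(500, 1500, 3500),
                      c(1200, 2600, 4200))
  sets <- make_sets(list(S1 = c("A", "B", "C")))
  res <- suppressWarnings(
    runAligator(snps, genes, sets, alphaGene = 0.5, windowBp = 0,
                nReplicates = 200, seed = 8, minGenes = 2))
  expect_true(all(res$summary$count == 0))
  expect_true(all(res$summary$excess_p == 1))
})
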