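test_that("window assignment is inclusive at the boundary and multi-gene", {
  genes <- gene_table(c("G1", "G2"), c(100000, 125000), c(110000, 135000))
  snps <- snp_table(c("edge", "outside", "inside", "between"),
                    c(80000, 79999, 101000, 117000),
                    c(0.5, 0.5, 0.5, 0.5))
  map <- mapSnpsToGenes(snps, genes, windowBp = 20000)
  expect_equal(snpToGenes(map)$edge, "G1")          # exactly 20 kb away
  expect_equal(snpToGenes(map)$outside, character(0))
  expect_equal(snpToGenes(map)$inside, "G1")        # in the gene body
  expect_setequal(snpToGenes(map)$between, c("G1", "G2"))  # within 20 kb of both
  ## unmapped SNPs stay in the domain
  expect_true("outside" %in% names(snpToGenes(map)))
})

test_that("widening the window never removes a SNP-gene pair", {
  set.seed(42)
  genes <- gene_table(sprintf("G%d", 1:8), (1:8) * 50000, (1:8) * 50000 + 9999)
  snps <- snp_table(sprintf("s%d", 1:60), sample.int(5e5, 60), runif(60))
  pairs_at <- function(w) {
    m <- snpToGenes(mapSnpsToGenes(snps, genes, w))
    paste(rep(names(m), lengths(m)), unlist(m))
  }
  p10 <- pairs_at(10000); p20 <- pairs_at(20000); p50 <- pairs_at(50000)
  expect_true(all(p10 %in% p20))
  expect_true(all(p20 %in% p50))
})

test_that("region exclusion removes overlapping genes except kept ids", {
  ## five genes in the region plus boundary cases around [1000, 2000]
  genes <- gene_table(c("APOE", "R1", "R2", "R3", "R4",
                        "straddle_lo", "straddle_hi", "before", "after"),
                      c(1100, 1200, 1300, 1400, 1500, 900, 1950, 500, 2500),
                      c(1150, 1250, 1350, 1450, 1550, 1050, 2100, 999, 2600))
  kept <- excludeRegion(genes, "1", 1000, 2000, keep = "APOE")
  expect_setequal(kept$gene_id, c("APOE", "before", "after"))
  none <- excludeRegion(genes, "1", 1000, 2000)
  expect_setequal(none$gene_id, c("before", "after"))
  expect_warning(excludeRegion(genes, "1", 1000, 2000, keep = "GHOST"),
                 "GHOST")

  ## enumerate overlap cases against interval arithmetic
  for (i in seq_len(nrow(genes))) {
    overlaps <- genes$start_bp[i] <= 2000 && genes$end_bp[i] >= 1000
    expect_equal(!genes$gene_id[i] %in% none$gene_id, overlaps)
  }
  ## different chromosome is untouched
  g2 <- genes; g2$chrom <- "2"
  expect_equal(nrow(excludeRegion(g2, "1", 1000, 2000)), nrow(g2))
})

test_that("significant gene list uses strict p < alpha and matches a scan", {
  genes <- gene_table(c("GA", "GB", "GC", "GD"),
                      c(1000, 30000, 60000, 90000),
                      c(5000, 35000, 65000, 95000))
  snps <- snp_table(sprintf("s%d", 1:6),
                    c(2000, 2500, 31000, 61000, 91000, 91500),
                    c(0.0005, 0.5, 0.001, 0.02, 0.0009, 0.00001))
  map <- mapSnpsToGenes(snps, genes, windowBp = 1000)
  sig <- buildSignificantGeneList(map, snps, alphaGene = 0.001)
  ## s3 has p exactly = alpha: not counted (strict inequality)
  expect_setequal(listedGenes(sig), c("GA", "GD"))
  expect_equal(definingSnps(sig)$GA, "s1")
  expect_setequal(definingSnps(sig)$GD, c("s5", "s6"))

  ## brute-force scan over all SNP-gene pairs agrees
  g2s <- geneToSnps(map)
  brute <- names(g2s)[vapply(g2s, function(s)
    any(snps$p_value[match(s, snps$snp_id)] < 0.001), NA)]
  expect_setequal(listedGenes(sig), brute)

  ## list size non-increasing as alpha decreases
  sizes <- vapply(c(0.05, 0.01, 0.001, 1e-4),
                  function(a) length(suppressWarnings(
                    buildSignificantGeneList(map, snps, a))), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("LD clusters collapse to one representative with merged SNPs", {
  sig <- make_sig_list(list(CR1 = "s1", CR2 = c("s1", "s2"), IL1 = "s3",
                            ZZZ = "s9"))
  ld <- new("LdInfo", clusters = list(c("CR2", "CR1"),
                                      c("IL1", "IL2", "IL3"),
                                      "SINGLETON"))
  out <- collapseLdClusters(sig, ld)
  expect_setequal(listedGenes(out), c("CR1", "IL1", "ZZZ"))
  ## defining SNPs of removed members re-attributed to the representative
  expect_setequal(definingSnps(out)$CR1, c("s1", "s2"))
  ## cluster with one listed gene is a no-op
  expect_equal(definingSnps(out)$IL1, "s3")

  ## three-gene cluster, two listed: union preserved
  sig2 <- make_sig_list(list(A1 = c("x1"), A3 = c("x2", "x3"), B = "y"))
  out2 <- collapseLdClusters(sig2, new("LdInfo", clusters = list(c("A3", "A1", "A2"))))
  expect_setequal(listedGenes(out2), c("A1", "B"))
  expect_setequal(definingSnps(out2)$A1, c("x1", "x2", "x3"))
})

test_that("SnpGeneMap validity rejects inconsistent edge lists", {
  expect_error(new("SnpGeneMap", windowBp = 0,
                   snpToGenes = list(s1 = "A"),
                   geneToSnps = list(A = c("s1", "s2"))),
               "disagree")
})
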