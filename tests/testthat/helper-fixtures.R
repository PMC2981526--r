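## Small in-code fixtures shared across test files.

snp_table <- function(ids, pos, p, chrom = "1", chi2 = NULL) {
  out <- data.frame(snp_id = ids, chrom = chrom, pos_bp = as.integer(pos),
                    p_value = p, stringsAsFactors = FALSE)
  if (!is.null(chi2)) out$chi2 <- chi2
  out
}

gene_table <- function(ids, start, end, chrom = "1") {
  data.frame(gene_id = ids, chrom = chrom, start_bp = as.integer(start),
             end_bp = as.integer(end), stringsAsFactors = FALSE)
}

make_sets <- function(genes, source = "custom") {
  new("GeneSetCollection",
      setIds = names(genes),
      setNames = names(genes),
      source = rep(source, length(genes)),
      genes = lapply(genes, as.character))
}

make_sig_list <- function(defining, alpha = 0.001) {
  new("SignificantGeneList", alphaGene = alpha,
      genes = names(defining), definingSnps = lapply(defining, as.character))
}

## a handcrafted map: s1->A; s2->A,B; s3->B; s4->C; s5 unmapped
toy_map <- function() {
  new("SnpGeneMap", windowBp = 0,
      snpToGenes = list(s1 = "A", s2 = c("A", "B"), s3 = "B",
                        s4 = "C", s5 = character(0)),
      geneToSnps = list(A = c("s1", "s2"), B = c("s2", "s3"), C = "s4"))
}

## GenotypeDataset straight from dosage columns
make_dataset <- function(dosages, pheno, snp_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(snp_ids)) snp_ids <- sprintf("rs%03d", seq_len(ncol(dosages)))
  new("GenotypeDataset", dosages = dosages,
      phenotype = factor(pheno, levels = c("control", "case")),
      individualIds = sprintf("i%04d", seq_len(nrow(dosages))),
      snpInfo = data.frame(snp_id = snp_ids, chrom = "1",
                           pos_bp = seq_len(ncol(dosages)) * 1000L,
                           stringsAsFactors = FALSE))
}

## brute-force maximum bipartite matching by enumeration of injective
## SNP assignments (oracle for countCategoryHits)
brute_matching <- function(defining) {
  genes <- names(defining)
  snps <- unique(unlist(defining))
  best <- 0L
  n <- length(genes)
  recurse <- function(i, used, size) {
    if (size + (n - i + 1) <= best) return()
    if (i > n) { best <<- max(best, size); return() }
    for (s in defining[[i]])
      if (!s %in% used) recurse(i + 1, c(used, s), size + 1L)
    recurse(i + 1, used, size)  # leave gene i unmatched
  }
  recurse(1L, character(0), 0L)
  best
}
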