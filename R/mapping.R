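## SNP-to-gene assignment under the symmetric 20 kb window rule, removal
## of genes in an LD-contaminated region while keeping a nominated gene
## (the APOE situation), collapsing of LD-linked genes into single
## signals, and construction of the significant gene list that seeds the
## enrichment analysis.

#' Assign SNPs to genes by a symmetric base-pair window
#'
#' A SNP is assigned to a gene when it lies on the same chromosome within
#' \code{[start_bp - windowBp, end_bp + windowBp]} (closed bounds: a SNP
#' at exactly the window edge is assigned). SNPs within the window of
#' several genes are assigned to all of them. SNPs mapping to no gene stay
#' in the map's domain with empty gene sets, so resampling draws from all
#' tested SNPs.
#'
#' @param snps SNP table (see [checkSnpTable()]).
#' @param genes gene table (see [checkGeneTable()]).
#' @param windowBp window size in base pairs; default 20000.
#' @return a \linkS4class{SnpGeneMap}.
#' @export
mapSnpsToGenes <- function(snps, genes, windowBp = 20000) {
  checkSnpTable(snps)
  checkGeneTable(genes)
  stopifnot(windowBp >= 0)
  snp_gr <- GenomicRanges::GRanges(
    normalizeChrom(snps$chrom),
    IRanges::IRanges(snps$pos_bp, width = 1L))
  gene_gr <- GenomicRanges::GRanges(
    normalizeChrom(genes$chrom),
    IRanges::IRanges(pmax(1L, genes$start_bp - as.integer(windowBp)),
                     genes$end_bp + as.integer(windowBp)))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  s_idx <- S4Vectors::queryHits(hits)
  g_idx <- S4Vectors::subjectHits(hits)
  s2g <- stats::setNames(vector("list", nrow(snps)), snps$snp_id)
  s2g[] <- list(character(0))
  if (length(s_idx)) {
    sp <- split(genes$gene_id[g_idx], factor(s_idx, levels = seq_len(nrow(snps))))
    s2g <- stats::setNames(lapply(sp, as.character), snps$snp_id)
  }
  g2s <- stats::setNames(vector("list", nrow(genes)), genes$gene_id)
  g2s[] <- list(character(0))
  if (length(g_idx)) {
    sp <- split(snps$snp_id[s_idx], factor(g_idx, levels = seq_len(nrow(genes))))
    g2s <- stats::setNames(lapply(sp, as.character), genes$gene_id)
  }
  new("SnpGeneMap", windowBp = as.numeric(windowBp),
      snpToGenes = s2g, geneToSnps = g2s)
}

#' Remove genes overlapping a genomic region, keeping nominated genes
#'
#' Drops every gene with any base of overlap with the region, except ids
#' listed in \code{keep}. Intended for regions where long-range LD with
#' one very strong signal contaminates neighbouring genes (e.g. removing
#' the genes around APOE while retaining APOE itself).
#'
#' @param genes gene table.
#' @param chrom chromosome of the region (\code{"chr"} prefix tolerated).
#' @param startBp,endBp region bounds, 1-based inclusive.
#' @param keep character vector of gene ids exempt from removal; ids
#'   absent from \code{genes} produce a warning, not an error.
#' @return the filtered gene table.
#' @export
excludeRegion <- function(genes, chrom, startBp, endBp, keep = character()) {
  checkGeneTable(genes)
  stopifnot(startBp <= endBp)
  missing_keep <- setdiff(keep, genes$gene_id)
  if (length(missing_keep))
    warning("keep id(s) absent from gene table: ",
            paste(missing_keep, collapse = ", "))
  in_region <- normalizeChrom(genes$chrom) == normalizeChrom(chrom) &
    genes$start_bp <= endBp & genes$end_bp >= startBp
  drop <- in_region & !genes$gene_id %in% keep
  genes[!drop, , drop = FALSE]
}

#' Build the significant gene list
#'
#' Lists every mapped gene having at least one assigned SNP with
#' association p-value strictly below \code{alphaGene}, recording those
#' defining SNPs per gene.
#'
#' @param map a \linkS4class{SnpGeneMap}.
#' @param snps SNP table with \code{p_value}.
#' @param alphaGene SNP significance threshold in (0, 1); strict
#'   inequality.
#' @return a \linkS4class{SignificantGeneList}; empty (with a warning)
#'   when no gene qualifies.
#' @export
buildSignificantGeneList <- function(map, snps, alphaGene = 0.001) {
  stopifnot(is(map, "SnpGeneMap"), alphaGene > 0, alphaGene < 1)
  checkSnpTable(snps)
  sig_snps <- snps$snp_id[snps$p_value < alphaGene]
  g2s <- map@geneToSnps
  def <- lapply(g2s, function(s) intersect(s, sig_snps))
  hit <- lengths(def) > 0L
  if (!any(hit))
    warning("no gene has a SNP with p < ", alphaGene)
  new("SignificantGeneList", alphaGene = alphaGene,
      genes = names(g2s)[hit], definingSnps = def[hit])
}

#' Collapse LD-linked genes into single signals
#'
#' Each cluster of gene ids in \code{ld} that intersects the significant
#' gene list is represented by exactly one retained gene — the
#' lexicographically smallest listed id — and the defining SNPs of the
#' removed members are re-attributed to the representative (the CR1/CR2
#' treatment: two adjacent genes tagging one locus count once).
#'
#' @param list a \linkS4class{SignificantGeneList}.
#' @param ld an \linkS4class{LdInfo}; its \code{clusters} hold the gene
#'   groups. Clusters containing no listed gene are no-ops.
#' @return a collapsed \linkS4class{SignificantGeneList}.
#' @export
collapseLdClusters <- function(list, ld) {
  stopifnot(is(list, "SignificantGeneList"), is(ld, "LdInfo"))
  genes <- list@genes
  def <- list@definingSnps
  for (cl in ld@clusters) {
    present <- sort(intersect(cl, genes))
    if (length(present) < 2L) next
    rep_gene <- present[1]
    def[[rep_gene]] <- sort(unique(unlist(def[present])))
    drop <- present[-1]
    genes <- setdiff(genes, drop)
    def[drop] <- NULL
  }
  new("SignificantGeneList", alphaGene = list@alphaGene,
      genes = genes, definingSnps = def[genes])
}
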