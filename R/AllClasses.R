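#' @import methods
#' @importFrom S4Vectors isSingleNumber isSingleString
NULL

## Central S4 containers. SNP association records and gene models travel as
## validated data.frames (see checkSnpTable()/checkGeneTable()); the objects
## below carry structure that plain tables cannot express.

#' GeneSetCollection: named gene categories
#'
#' A collection of gene sets (GO/KEGG/MGI-derived or custom), each a set of
#' gene identifiers with a display name and a source label.
#'
#' @slot setIds character vector of unique set identifiers.
#' @slot setNames character vector of display names, parallel to
#'   \code{setIds}.
#' @slot source character vector of source labels (\code{"GO"},
#'   \code{"KEGG"}, \code{"MGI"} or \code{"custom"}), parallel to
#'   \code{setIds}.
#' @slot genes list of character vectors of member gene ids, parallel to
#'   \code{setIds}; duplicates within a set are not allowed.
#'
#' @seealso [readGmt()], [restrictSets()], [geneSets()]
#' @export
setClass("GeneSetCollection",
  representation(
    setIds   = "character",
    setNames = "character",
    source   = "character",
    genes    = "list"
  )
)

setValidity("GeneSetCollection", function(object) {
  n <- length(object@setIds)
  if (length(object@setNames) != n || length(object@source) != n ||
      length(object@genes) != n)
    return("setIds, setNames, source and genes must have equal length")
  if (anyDuplicated(object@setIds))
    return("set ids must be unique")
  bad <- !object@source %in% c("GO", "KEGG", "MGI", "custom")
  if (any(bad))
    return("source must be one of GO, KEGG, MGI, custom")
  for (i in seq_len(n)) {
    g <- object@genes[[i]]
    if (!is.character(g) || length(g) == 0L)
      return(sprintf("set '%s' has no genes", object@setIds[i]))
    if (anyDuplicated(g))
      return(sprintf("set '%s' contains duplicated gene ids",
                     object@setIds[i]))
  }
  TRUE
})

#' LdInfo: pairwise linkage disequilibrium and signal clusters
#'
#' Symmetric pairwise r-squared between SNPs, plus optional clusters of
#' gene (or SNP) identifiers that are to be collapsed into a single
#' association signal (e.g. CR1/CR2-style adjacent genes tagging one locus).
#'
#' @slot pairs data.frame with columns \code{snp_a}, \code{snp_b},
#'   \code{r2}; each unordered pair stored once, \code{r2} in [0, 1].
#' @slot clusters list of character vectors; identifiers within a vector
#'   are treated as one signal.
#'
#' @seealso [readLdTable()], [ldR2()], [collapseLdClusters()]
#' @export
setClass("LdInfo",
  representation(pairs = "data.frame", clusters = "list"),
  prototype(
    pairs = data.frame(snp_a = character(), snp_b = character(),
                       r2 = numeric(), stringsAsFactors = FALSE),
    clusters = list()
  )
)

setValidity("LdInfo", function(object) {
  p <- object@pairs
  if (!all(c("snp_a", "snp_b", "r2") %in% names(p)))
    return("pairs must have columns snp_a, snp_b, r2")
  if (nrow(p) && (any(p$r2 < 0) || any(p$r2 > 1)))
    return("r2 values must lie in [0, 1]")
  if (nrow(p) && any(p$snp_a == p$snp_b & p$r2 != 1))
    return("r2 of a SNP with itself must be 1")
  for (cl in object@clusters)
    if (!is.character(cl) || length(cl) < 1L)
      return("clusters must be non-empty character vectors")
  TRUE
})

#' GenotypeDataset: case-control individuals by SNP dosages
#'
#' Individual-level genotypes for permutation testing. Dosages count minor
#' alleles (0/1/2, NA for missing); column order matches \code{snpInfo}.
#'
#' @slot dosages integer matrix, individuals x SNPs; entries 0, 1, 2 or NA.
#' @slot phenotype factor with levels \code{control}, \code{case}, one per
#'   individual.
#' @slot individualIds character vector of unique individual ids.
#' @slot snpInfo data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos_bp} describing the dosage columns.
#'
#' @seealso [simulateDataset()], [computeSummaryStats()]
#' @export
setClass("GenotypeDataset",
  representation(
    dosages       = "matrix",
    phenotype     = "factor",
    individualIds = "character",
    snpInfo       = "data.frame"
  )
)

setValidity("GenotypeDataset", function(object) {
  d <- object@dosages
  if (nrow(d) != length(object@phenotype) ||
      nrow(d) != length(object@individualIds))
    return("dosage rows must match phenotype and individual ids")
  if (!identical(levels(object@phenotype), c("control", "case")))
    return("phenotype levels must be control, case")
  if (sum(object@phenotype == "case") < 1L ||
      sum(object@phenotype == "control") < 1L)
    return("need at least one case and one control")
  if (ncol(d) != nrow(object@snpInfo))
    return("dosage columns must match snpInfo rows")
  if (!all(c("snp_id", "chrom", "pos_bp") %in% names(object@snpInfo)))
    return("snpInfo must have columns snp_id, chrom, pos_bp")
  v <- d[!is.na(d)]
  if (length(v) && (any(v < 0) || any(v > 2)))
    return("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(object@individualIds))
    return("individual ids must be unique")
  TRUE
})

#' SnpGeneMap: bidirectional SNP-to-gene assignment under a window rule
#'
#' Records which SNPs are assigned to which genes under a symmetric
#' base-pair window around the gene body. SNPs that map to no gene are kept
#' in the map's domain with empty gene sets, so that resampling draws from
#' all tested SNPs.
#'
#' @slot windowBp single non-negative integer, the assignment window.
#' @slot snpToGenes named list: snp_id -> character vector of gene ids
#'   (possibly empty).
#' @slot geneToSnps named list: gene_id -> character vector of snp ids.
#'
#' @seealso [mapSnpsToGenes()], [snpToGenes()], [geneToSnps()]
#' @export
setClass("SnpGeneMap",
  representation(
    windowBp   = "numeric",
    snpToGenes = "list",
    geneToSnps = "list"
  )
)

setValidity("SnpGeneMap", function(object) {
  if (!isSingleNumber(object@windowBp) || object@windowBp < 0)
    return("windowBp must be a single non-negative number")
  if (is.null(names(object@snpToGenes)) && length(object@snpToGenes))
    return("snpToGenes must be named by snp id")
  if (is.null(names(object@geneToSnps)) && length(object@geneToSnps))
    return("geneToSnps must be named by gene id")
  ## bidirectional consistency: the two edge lists must be the same set
  fwd <- paste(rep(names(object@snpToGenes), lengths(object@snpToGenes)),
               unlist(object@snpToGenes, use.names = FALSE))
  rev <- paste(unlist(object@geneToSnps, use.names = FALSE),
               rep(names(object@geneToSnps), lengths(object@geneToSnps)))
  if (length(fwd) != length(rev) || !setequal(fwd, rev))
    return("snpToGenes and geneToSnps disagree on the SNP-gene assignments")
  TRUE
})

#' SignificantGeneList: genes defined by at least one significant SNP
#'
#' The gene list that seeds the enrichment analysis: genes with at least
#' one assigned SNP whose association p-value is strictly below
#' \code{alphaGene}.
#'
#' @slot alphaGene single number in (0, 1), the SNP significance threshold.
#' @slot genes character vector of listed gene ids.
#' @slot definingSnps named list: gene_id -> character vector of the SNPs
#'   with p below threshold that put the gene on the list.
#'
#' @seealso [buildSignificantGeneList()], [collapseLdClusters()]
#' @export
setClass("SignificantGeneList",
  representation(
    alphaGene    = "numeric",
    genes        = "character",
    definingSnps = "list"
  )
)

setValidity("SignificantGeneList", function(object) {
  if (!isSingleNumber(object@alphaGene) ||
      object@alphaGene <= 0 || object@alphaGene >= 1)
    return("alphaGene must be a single number in (0, 1)")
  if (anyDuplicated(object@genes))
    return("gene list must not contain duplicates")
  if (!setequal(names(object@definingSnps), object@genes))
    return("definingSnps must be named exactly by the listed genes")
  if (any(lengths(object@definingSnps) == 0L))
    return("every listed gene needs at least one defining SNP")
  TRUE
})

#' ReplicateGeneLists: the SNP-resampling null for enrichment
#'
#' Replicate gene lists of a fixed target length, built by sampling SNPs
#' uniformly without replacement and accumulating their mapped genes. Each
#' gene on a replicate list carries the single sampled SNP that added it as
#' its defining SNP, so the one-SNP-one-gene counting rule applies to null
#' lists exactly as to the observed list.
#'
#' @slot nReplicates number of replicate lists.
#' @slot targetLength exact length of every list.
#' @slot lists list of character vectors of gene ids, each of length
#'   \code{targetLength}, all distinct within a list.
#' @slot definingSnps list of character vectors parallel to \code{lists}:
#'   element i gives, for each gene of list i, the sampled SNP that added it.
#' @slot seed the seed the lists were generated under.
#'
#' @seealso [generateReplicateLists()], [replicateHitMatrix()]
#' @export
setClass("ReplicateGeneLists",
  representation(
    nReplicates  = "integer",
    targetLength = "integer",
    lists        = "list",
    definingSnps = "list",
    seed         = "integer"
  )
)

setValidity("ReplicateGeneLists", function(object) {
  if (length(object@lists) != object@nReplicates)
    return("number of stored lists must equal nReplicates")
  if (length(object@definingSnps) != object@nReplicates)
    return("definingSnps must be parallel to lists")
  for (i in seq_along(object@lists)) {
    l <- object@lists[[i]]
    if (length(l) != object@targetLength)
      return(sprintf("replicate %d has length %d, expected %d",
                     i, length(l), object@targetLength))
    if (anyDuplicated(l))
      return(sprintf("replicate %d contains duplicate genes", i))
    if (length(object@definingSnps[[i]]) != length(l))
      return(sprintf("replicate %d: defining SNPs not parallel to genes", i))
  }
  TRUE
})
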