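#' @rdname GeneSetCollection-class
#' @param x a \linkS4class{GeneSetCollection}.
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("setSource", function(x) standardGeneric("setSource"))

#' @rdname SnpGeneMap-class
#' @param x a \linkS4class{SnpGeneMap}.
#' @export
setGeneric("snpToGenes", function(x) standardGeneric("snpToGenes"))

#' @rdname SnpGeneMap-class
#' @export
setGeneric("geneToSnps", function(x) standardGeneric("geneToSnps"))

#' @rdname SnpGeneMap-class
#' @export
setGeneric("windowBp", function(x) standardGeneric("windowBp"))

#' @rdname SignificantGeneList-class
#' @param x a \linkS4class{SignificantGeneList}.
#' @export
setGeneric("listedGenes", function(x) standardGeneric("listedGenes"))

#' @rdname SignificantGeneList-class
#' @export
setGeneric("definingSnps", function(x) standardGeneric("definingSnps"))

#' @rdname SignificantGeneList-class
#' @export
setGeneric("alphaGene", function(x) standardGeneric("alphaGene"))

#' @rdname GenotypeDataset-class
#' @param x a \linkS4class{GenotypeDataset}.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeDataset-class
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname GenotypeDataset-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname ReplicateGeneLists-class
#' @param x a \linkS4class{ReplicateGeneLists}.
#' @export
setGeneric("replicateLists", function(x) standardGeneric("replicateLists"))

#' @rdname LdInfo-class
#' @param x an \linkS4class{LdInfo}.
#' @export
setGeneric("ldPairs", function(x) standardGeneric("ldPairs"))

#' @rdname LdInfo-class
#' @export
setGeneric("ldClusters", function(x) standardGeneric("ldClusters"))
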