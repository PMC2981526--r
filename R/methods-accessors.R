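#' @rdname GeneSetCollection-class
#' @export
setMethod("setIds", "GeneSetCollection", function(x) x@setIds)

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection",
          function(x) stats::setNames(x@genes, x@setIds))

#' @rdname GeneSetCollection-class
#' @export
setMethod("setSource", "GeneSetCollection",
          function(x) stats::setNames(x@source, x@setIds))

#' @rdname GeneSetCollection-class
#' @param i set ids or indices to keep.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@setIds)
  if (anyNA(i)) stop("unknown set id in subset")
  new("GeneSetCollection",
      setIds = x@setIds[i], setNames = x@setNames[i],
      source = x@source[i], genes = x@genes[i])
})

#' @rdname GeneSetCollection-class
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@setIds))

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@setIds), "sets\n")
  if (length(object@setIds)) {
    sz <- lengths(object@genes)
    cat("  set sizes:", min(sz), "-", max(sz),
        "(median", stats::median(sz), ")\n")
    cat("  sources:", paste(names(table(object@source)), collapse = ", "),
        "\n")
  }
})

#' @rdname SnpGeneMap-class
#' @export
setMethod("snpToGenes", "SnpGeneMap", function(x) x@snpToGenes)

#' @rdname SnpGeneMap-class
#' @export
setMethod("geneToSnps", "SnpGeneMap", function(x) x@geneToSnps)

#' @rdname SnpGeneMap-class
#' @export
setMethod("windowBp", "SnpGeneMap", function(x) x@windowBp)

setMethod("show", "SnpGeneMap", function(object) {
  n_mapped <- sum(lengths(object@snpToGenes) > 0L)
  cat("SnpGeneMap:", length(object@snpToGenes), "SNPs (",
      n_mapped, "mapped ),", length(object@geneToSnps),
      "genes, window", object@windowBp, "bp\n")
})

#' @rdname SignificantGeneList-class
#' @export
setMethod("listedGenes", "SignificantGeneList", function(x) x@genes)

#' @rdname SignificantGeneList-class
#' @export
setMethod("definingSnps", "SignificantGeneList", function(x) x@definingSnps)

#' @rdname SignificantGeneList-class
#' @export
setMethod("alphaGene", "SignificantGeneList", function(x) x@alphaGene)

#' @rdname SignificantGeneList-class
#' @export
setMethod("length", "SignificantGeneList", function(x) length(x@genes))

setMethod("show", "SignificantGeneList", function(object) {
  cat("SignificantGeneList:", length(object@genes),
      "genes at SNP p <", object@alphaGene, "\n")
})

#' @rdname GenotypeDataset-class
#' @export
setMethod("dosages", "GenotypeDataset", function(x) x@dosages)

#' @rdname GenotypeDataset-class
#' @export
setMethod("phenotype", "GenotypeDataset", function(x) x@phenotype)

#' @rdname GenotypeDataset-class
#' @export
setMethod("snpInfo", "GenotypeDataset", function(x) x@snpInfo)

#' @rdname GenotypeDataset-class
#' @export
setMethod("dim", "GenotypeDataset", function(x) dim(x@dosages))

setMethod("show", "GenotypeDataset", function(object) {
  cat("GenotypeDataset:", nrow(object@dosages), "individuals (",
      sum(object@phenotype == "case"), "cases /",
      sum(object@phenotype == "control"), "controls ) x",
      ncol(object@dosages), "SNPs\n")
})

#' @rdname ReplicateGeneLists-class
#' @export
setMethod("replicateLists", "ReplicateGeneLists", function(x) x@lists)

#' @rdname ReplicateGeneLists-class
#' @export
setMethod("length", "ReplicateGeneLists", function(x) x@nReplicates)

setMethod("show", "ReplicateGeneLists", function(object) {
  cat("ReplicateGeneLists:", object@nReplicates, "lists of",
      object@targetLength, "genes (seed", object@seed, ")\n")
})

#' @rdname LdInfo-class
#' @export
setMethod("ldPairs", "LdInfo", function(x) x@pairs)

#' @rdname LdInfo-class
#' @export
setMethod("ldClusters", "LdInfo", function(x) x@clusters)

setMethod("show", "LdInfo", function(object) {
  cat("LdInfo:", nrow(object@pairs), "SNP pairs,",
      length(object@clusters), "signal clusters\n")
})

#' Look up pairwise r-squared values
#'
#' Symmetric lookup: \code{ldR2(ld, a, b)} equals \code{ldR2(ld, b, a)};
#' a SNP with itself returns 1; pairs absent from the table return
#' \code{NA} (callers decide how to treat unknown LD).
#'
#' @param ld an \linkS4class{LdInfo}.
#' @param a,b character vectors of SNP ids (recycled to common length).
#' @return numeric vector of r-squared values.
#' @export
ldR2 <- function(ld, a, b) {
  stopifnot(is(ld, "LdInfo"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  key <- ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  p <- ld@pairs
  tab_key <- ifelse(p$snp_a <= p$snp_b,
                    paste(p$snp_a, p$snp_b, sep = "\r"),
                    paste(p$snp_b, p$snp_a, sep = "\r"))
  out <- p$r2[match(key, tab_key)]
  out[a == b] <- 1
  out
}
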