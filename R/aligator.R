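## The resampling enrichment engine. A list of significant genes (from
## significant SNPs) is tested for over-representation in gene categories
## against replicate gene lists of the same length built by random SNP
## sampling. Sampling SNPs rather than genes makes genes with many SNPs
## proportionally more likely to enter null lists, which corrects the
## gene-size bias that a naive gene-sampling (hypergeometric) test
## suffers; counting each gene once and allowing any one SNP to support at
## most one gene per category removes the influence of within-gene LD and
## of SNPs shared by overlapping genes. All permutation p-values use the
## add-one (r+1)/(n+1) convention and so are bounded below by 1/(n+1).

#' Restrict a gene-set collection to a gene universe
#'
#' Intersects every set with \code{universe} and drops sets left with
#' fewer than \code{minGenes} members. Enrichment analyses only consider
#' genes that received at least one SNP, and categories too small to carry
#' two independent signals are uninformative.
#'
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param universe character vector of gene ids to keep.
#' @param minGenes minimum post-restriction set size (default 3).
#' @return a restricted \linkS4class{GeneSetCollection}.
#' @export
restrictSets <- function(sets, universe, minGenes = 3) {
  stopifnot(is(sets, "GeneSetCollection"))
  genes <- lapply(sets@genes, intersect, y = universe)
  keep <- lengths(genes) >= minGenes
  new("GeneSetCollection",
      setIds = sets@setIds[keep], setNames = sets@setNames[keep],
      source = sets@source[keep], genes = genes[keep])
}

#' Generate replicate gene lists by random SNP sampling
#'
#' Builds \code{nReplicates} null gene lists, each of exactly
#' \code{targetLength} distinct genes. SNP ids are sampled uniformly
#' without replacement from \code{snpIds}; each sampled SNP appends all
#' its mapped genes not already on the list; when an append would exceed
#' the target, the offending SNP's genes are added in random order and the
#' list truncated at exactly the target length. Each gene on a replicate
#' list records the sampled SNP that added it as its defining SNP.
#'
#' @param map a \linkS4class{SnpGeneMap}.
#' @param snpIds SNPs to sample from; defaults to the map's full SNP
#'   domain (all tested SNPs, mapped or not).
#' @param targetLength length of every replicate list; must not exceed the
#'   number of mappable genes.
#' @param nReplicates number of lists.
#' @param seed integer seed (same seed, same lists).
#' @return a \linkS4class{ReplicateGeneLists}.
#' @export
generateReplicateLists <- function(map, snpIds = names(snpToGenes(map)),
                                   targetLength, nReplicates, seed) {
  stopifnot(is(map, "SnpGeneMap"), nReplicates >= 1, targetLength >= 0)
  gene_ids <- names(map@geneToSnps)[lengths(map@geneToSnps) > 0L]
  if (length(gene_ids) == 0L)
    stop("the SNP-gene map contains no mappable genes")
  if (targetLength > length(gene_ids))
    stop("targetLength (", targetLength, ") exceeds the ",
         length(gene_ids), " mappable genes")
  s2g <- map@snpToGenes[snpIds]
  if (anyNA(names(s2g))) stop("snpIds absent from the map domain")
  gene_idx <- lapply(s2g, function(g) match(g, gene_ids))
  offsets <- c(0L, cumsum(lengths(gene_idx)))
  flat <- as.integer(unlist(gene_idx, use.names = FALSE)) - 1L
  if (is.null(flat)) flat <- integer(0)
  set.seed(seed)
  res <- cpp_replicate_lists(as.integer(offsets), flat,
                             length(gene_ids), as.integer(targetLength),
                             as.integer(nReplicates))
  lists <- lapply(res$genes, function(i) gene_ids[i])
  dsnps <- lapply(res$snps, function(i) snpIds[i])
  new("ReplicateGeneLists",
      nReplicates = as.integer(nReplicates),
      targetLength = as.integer(targetLength),
      lists = lists, definingSnps = dsnps, seed = as.integer(seed))
}

#' Count category hits under the one-SNP-one-gene rule
#'
#' The deduplicated hit count of a category: the size of a maximum
#' bipartite matching between the listed genes belonging to the category
#' and their defining SNPs, so that each SNP supports at most one gene and
#' each counted gene has a dedicated SNP. Two overlapping genes whose only
#' significant SNP is shared therefore count once. When no defining SNP is
#' shared the matching is trivially the number of listed genes in the
#' category; the matching solver (igraph) is only invoked when sharing
#' exists.
#'
#' @param list a \linkS4class{SignificantGeneList} (or a replicate list
#'   converted to one).
#' @param setGenes character vector of the category's member genes.
#' @param map unused; retained so callers can pass the
#'   \linkS4class{SnpGeneMap} alongside (the defining SNPs are already
#'   recorded on \code{list}).
#' @return integer hit count.
#' @export
countCategoryHits <- function(list, setGenes, map = NULL) {
  stopifnot(is(list, "SignificantGeneList"))
  g <- intersect(list@genes, setGenes)
  if (length(g) == 0L) return(0L)
  def <- list@definingSnps[g]
  all_snps <- unlist(def, use.names = FALSE)
  if (!anyDuplicated(all_snps)) return(length(g))
  ## maximum bipartite matching genes <-> defining SNPs
  snps <- unique(all_snps)
  edges <- cbind(rep(seq_along(g), lengths(def)),
                 length(g) + match(all_snps, snps))
  gr <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, length(g)), rep(TRUE, length(snps))),
    edges = as.vector(t(edges)))
  as.integer(igraph::max_bipartite_match(gr)$matching_size)
}

#' Hit-count matrix of replicate lists over a category collection
#'
#' Applies the same one-SNP-one-gene counting rule to every replicate
#' list: on a replicate list each gene has exactly one defining SNP (the
#' sampled SNP that added it), so a category's count is the number of
#' distinct defining SNPs among its listed member genes.
#'
#' @param replicates a \linkS4class{ReplicateGeneLists}.
#' @param sets a \linkS4class{GeneSetCollection} (already restricted to
#'   the mapped gene universe).
#' @return integer matrix, replicates x sets, with set ids as column
#'   names.
#' @export
replicateHitMatrix <- function(replicates, sets) {
  stopifnot(is(replicates, "ReplicateGeneLists"), is(sets, "GeneSetCollection"))
  universe <- unique(unlist(sets@genes, use.names = FALSE))
  n_cats <- length(sets@setIds)
  if (n_cats == 0L)
    return(matrix(0L, replicates@nReplicates, 0L))
  g2c <- split(rep(seq_len(n_cats), lengths(sets@genes)) - 1L,
               factor(unlist(sets@genes, use.names = FALSE), levels = universe))
  offsets <- c(0L, cumsum(lengths(g2c)))
  flat <- as.integer(unlist(g2c, use.names = FALSE))
  snp_universe <- unique(unlist(replicates@definingSnps, use.names = FALSE))
  rep_genes <- lapply(replicates@lists, function(l) {
    i <- match(l, universe)
    i[is.na(i)] <- 0L  # genes outside every set: harmless index 0 removed below
    i
  })
  rep_snps <- lapply(replicates@definingSnps,
                     function(s) match(s, snp_universe))
  for (r in seq_along(rep_genes)) {
    keep <- rep_genes[[r]] > 0L
    rep_genes[[r]] <- as.integer(rep_genes[[r]][keep])
    rep_snps[[r]] <- as.integer(rep_snps[[r]][keep])
  }
  H <- cpp_hit_counts(rep_genes, rep_snps, as.integer(offsets), flat,
                      n_cats, length(snp_universe))
  colnames(H) <- sets@setIds
  H
}

#' Enrichment p-value of one category against replicate hit counts
#'
#' Add-one empirical p-value: \code{(1 + #\{replicates with hits >=
#' observed\}) / (nReplicates + 1)}, together with the expected (mean
#' replicate) hit count.
#'
#' @param observedHits observed hit count from [countCategoryHits()].
#' @param repHits integer vector of the category's hit counts on each
#'   replicate list.
#' @return list with \code{p_enrich} and \code{expected}.
#' @export
categoryEnrichmentP <- function(observedHits, repHits) {
  B <- length(repHits)
  stopifnot(B >= 1)
  list(p_enrich = (1 + sum(repHits >= observedHits)) / (B + 1),
       expected = mean(repHits))
}

#' Leave-one-out enrichment p-values of the replicate lists themselves
#'
#' For every replicate r and category c, the enrichment p-value that
#' replicate r's list would receive were it the observed list, with the
#' remaining replicates as the null:
#' \code{(1 + #\{s != r : hits[s, c] >= hits[r, c]\}) / nReplicates}.
#' These drive the study-wide correction and the
#' excess-of-enriched-categories test.
#'
#' @param H replicate hit-count matrix from [replicateHitMatrix()].
#' @return numeric matrix of the same shape.
#' @export
leaveOneOutP <- function(H) {
  B <- nrow(H)
  P <- matrix(NA_real_, B, ncol(H), dimnames = dimnames(H))
  for (c in seq_len(ncol(H))) {
    h <- H[, c]
    tab <- tabulate(h + 1L, nbins = max(h) + 1L)
    cnt_ge <- rev(cumsum(rev(tab)))          # cnt_ge[k+1] = #{s: h_s >= k}
    P[, c] <- cnt_ge[h + 1L] / B             # (1 + (cnt_ge - 1)) / B
  }
  P
}

#' Study-wide corrected p-value
#'
#' The probability of observing, by chance, at least one category with an
#' enrichment p-value at least as small as \code{targetP}, estimated from
#' the leave-one-out p-values of the replicate lists:
#' \code{(1 + #\{replicates whose minimum category p <= targetP\}) /
#' (nReplicates + 1)}.
#'
#' @param targetP the category-specific enrichment p-value to correct.
#' @param repP leave-one-out p-value matrix from [leaveOneOutP()].
#' @return the study-wide p-value.
#' @export
studywideP <- function(targetP, repP) {
  minp <- apply(repP, 1L, min)
  (1 + sum(minp <= targetP)) / (nrow(repP) + 1)
}

#' Deduplicate categories with identical significant-gene sets
#'
#' Among result rows whose categories contain the same (non-empty) set of
#' significant genes, only the most significant row is kept (ties broken
#' by the lexicographically smallest set id). Rows with empty hit sets are
#' never collapsed — there is nothing shared to deduplicate.
#'
#' @param rows data.frame with at least \code{set_id} and \code{p_enrich}.
#' @param hitGeneSets named list (by set id) of each category's
#'   significant genes.
#' @return \code{rows} restricted to the kept categories.
#' @export
dedupIdenticalCategories <- function(rows, hitGeneSets) {
  keep <- .dedupKeepFlags(rows$set_id, rows$p_enrich, hitGeneSets)
  rows[keep, , drop = FALSE]
}

.dedupKeepFlags <- function(set_ids, p_enrich, hitGeneSets) {
  sig <- vapply(hitGeneSets[set_ids],
                function(g) paste(sort(g), collapse = "\r"), "")
  keep <- rep(TRUE, length(set_ids))
  nonempty <- nzchar(sig)
  for (s in unique(sig[nonempty])) {
    idx <- which(sig == s)
    if (length(idx) < 2L) next
    best <- idx[order(p_enrich[idx], set_ids[idx])][1]
    keep[setdiff(idx, best)] <- FALSE
  }
  keep
}

#' Excess-of-enriched-categories test
#'
#' Tests whether the number of significantly enriched categories (those
#' with enrichment p below a threshold, at least two signals, after
#' deduplication of identical significant-gene sets) is larger than
#' expected, by comparing it with the corresponding count of each
#' replicate list under the same rules.
#'
#' @param rows full enrichment table (one row per category, columns
#'   \code{set_id}, \code{n_sig}, \code{p_enrich}, \code{dedup_kept}).
#' @param H replicate hit-count matrix.
#' @param repP leave-one-out p-value matrix.
#' @param replicates the \linkS4class{ReplicateGeneLists}.
#' @param sets the restricted \linkS4class{GeneSetCollection}.
#' @param thresholds enrichment p-value thresholds.
#' @return data.frame with columns \code{threshold}, \code{count},
#'   \code{excess_p}.
#' @export
excessEnrichedCategories <- function(rows, H, repP, replicates, sets,
                                     thresholds = c(0.05, 0.01, 0.001)) {
  members <- stats::setNames(sets@genes, sets@setIds)
  B <- nrow(H)
  out <- lapply(thresholds, function(t) {
    obs_count <- sum(rows$dedup_kept & rows$p_enrich < t & rows$n_sig >= 2L)
    flag <- repP < t & H >= 2L
    rep_counts <- rowSums(flag)
    ## dedup identical hit-gene sets, only where a replicate flags >= 2
    for (r in which(rep_counts >= 2L)) {
      flagged <- which(flag[r, ])
      lst <- replicates@lists[[r]]
      sig <- vapply(flagged, function(c)
        paste(sort(intersect(lst, members[[c]])), collapse = "\r"), "")
      rep_counts[r] <- length(unique(sig))
    }
    data.frame(threshold = t, count = obs_count,
               excess_p = (1 + sum(rep_counts >= obs_count)) / (B + 1))
  })
  do.call(rbind, out)
}

#' Run the full resampling enrichment analysis
#'
#' End-to-end driver: maps SNPs to genes under the window rule, builds the
#' significant gene list (optionally collapsing LD-linked genes into
#' single signals), restricts the category collection to mapped genes,
#' generates replicate gene lists by SNP resampling, and computes per-
#' category enrichment p-values, study-wide corrected p-values, the
#' deduplication flags and the excess-of-enriched-categories summary.
#'
#' @param snps SNP association table.
#' @param genes gene table (after any region exclusion).
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param alphaGene SNP threshold defining the significant gene list.
#' @param windowBp SNP-to-gene assignment window.
#' @param nReplicates number of replicate gene lists.
#' @param seed integer seed.
#' @param ld optional \linkS4class{LdInfo} whose clusters collapse
#'   LD-linked genes.
#' @param minGenes minimum post-restriction category size.
#' @param selectThreshold enrichment threshold for the
#'   \code{enriched_flag} column.
#' @param thresholds thresholds of the excess-of-enriched-categories
#'   summary.
#' @return list with elements \code{enrichment} (data.frame: set_id,
#'   n_genes_mapped, n_sig, expected, p_enrich, studywide_p,
#'   enriched_flag, dedup_kept), \code{summary} (from
#'   [excessEnrichedCategories()]), \code{sigList}, \code{map},
#'   \code{replicates}, \code{H}, \code{repP}, and \code{sets} (the
#'   restricted collection).
#' @export
runAligator <- function(snps, genes, sets, alphaGene = 0.001,
                        windowBp = 20000, nReplicates = 5000, seed = 1L,
                        ld = NULL, minGenes = 3, selectThreshold = 0.05,
                        thresholds = c(0.05, 0.01, 0.001)) {
  map <- mapSnpsToGenes(snps, genes, windowBp)
  sigList <- buildSignificantGeneList(map, snps, alphaGene)
  if (!is.null(ld) && length(ld@clusters))
    sigList <- collapseLdClusters(sigList, ld)
  mappable <- names(map@geneToSnps)[lengths(map@geneToSnps) > 0L]
  rsets <- restrictSets(sets, mappable, minGenes)
  target <- length(sigList@genes)
  replicates <- generateReplicateLists(map, names(map@snpToGenes),
                                       targetLength = target,
                                       nReplicates = nReplicates,
                                       seed = seed)
  H <- replicateHitMatrix(replicates, rsets)
  repP <- leaveOneOutP(H)
  n_cats <- length(rsets@setIds)
  obs_hits <- integer(n_cats)
  hit_sets <- stats::setNames(vector("list", n_cats), rsets@setIds)
  for (c in seq_len(n_cats)) {
    obs_hits[c] <- countCategoryHits(sigList, rsets@genes[[c]])
    hit_sets[[c]] <- intersect(sigList@genes, rsets@genes[[c]])
  }
  p_enrich <- numeric(n_cats); expected <- numeric(n_cats)
  for (c in seq_len(n_cats)) {
    e <- categoryEnrichmentP(obs_hits[c], H[, c])
    p_enrich[c] <- e$p_enrich; expected[c] <- e$expected
  }
  minp <- if (n_cats) apply(repP, 1L, min) else numeric(0)
  studywide <- vapply(p_enrich,
                      function(tp) (1 + sum(minp <= tp)) / (nrow(repP) + 1),
                      0)
  enrichment <- data.frame(
    set_id = rsets@setIds,
    n_genes_mapped = lengths(rsets@genes),
    n_sig = obs_hits,
    expected = expected,
    p_enrich = p_enrich,
    studywide_p = studywide,
    enriched_flag = p_enrich < selectThreshold & obs_hits >= 2L,
    stringsAsFactors = FALSE
  )
  enrichment$dedup_kept <- .dedupKeepFlags(enrichment$set_id,
                                           enrichment$p_enrich, hit_sets)
  summary <- excessEnrichedCategories(enrichment, H, repP, replicates,
                                      rsets, thresholds)
  list(enrichment = enrichment, summary = summary, sigList = sigList,
       map = map, replicates = replicates, H = H, repP = repP,
       sets = rsets)
}
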