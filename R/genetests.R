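## Gene- and set-level permutation tests that validate the resampling
## enrichment results: gene-wide correction of the best single-SNP
## p-value, the average allelic chi-squared set test (both with nulls
## generated by permuting disease status among individuals, which
## preserves inter-SNP LD), the Simes gene-wide p-value, and rank-based
## gene-set enrichment (GSEA) on -log Simes scores.

#' Simes gene-wide p-value
#'
#' With order statistics \eqn{p_{(1)} \le \dots \le p_{(m)}}, returns
#' \eqn{\min_i m\, p_{(i)} / i}. Never exceeds \eqn{m \cdot \min(p)} and
#' never falls below \eqn{\min(p)}; equals the single p-value for m = 1.
#'
#' @param ps numeric vector of p-values in (0, 1]; must be non-empty.
#' @return the Simes-corrected p-value in (0, 1].
#' @export
simesP <- function(ps) {
  if (length(ps) == 0L) stop("simesP needs at least one p-value")
  if (any(ps <= 0 | ps > 1)) stop("p-values must lie in (0, 1]")
  m <- length(ps)
  min(m * sort(ps) / seq_len(m))
}

## n x B matrix of permuted case indicators (column = one permutation).
## Drawn as a uniform random subset of individuals, selected in the
## canonical order of sorted individual ids, so that storing the same
## individuals in a different row order yields identical permutations
## (and hence identical permutation p-values) at the same seed.
.permIndicator <- function(dataset, B) {
  ids <- dataset@individualIds
  n <- length(ids)
  n_case <- sum(dataset@phenotype == "case")
  ord <- order(ids)
  Y <- matrix(0L, n, B)
  for (b in seq_len(B))
    Y[ord[sample.int(n, n_case)], b] <- 1L
  Y
}

## allelic chi-squared of every SNP under every permuted phenotype.
## D: individuals x SNPs dosages (NA = missing); Y: individuals x B
## permuted case indicators. Returns SNPs x B chi-squared values.
.chi2Perm <- function(D, Y) {
  obs <- !is.na(D)
  D0 <- D; D0[!obs] <- 0L
  a <- crossprod(D0, Y)                      # minor alleles among cases
  caseN <- crossprod(obs, Y)                 # non-missing cases per SNP
  A <- colSums(D0)                           # minor alleles overall
  N <- colSums(obs)                          # non-missing overall
  b <- 2 * caseN - a
  cc <- A - a
  dd <- 2 * (N - caseN) - cc
  n <- a + b + cc + dd
  num <- n * (a * dd - b * cc)^2
  den <- (a + b) * (cc + dd) * (a + cc) * (b + dd)
  chi2 <- num / den
  chi2[den == 0] <- 0
  chi2
}

#' Gene-wide corrected minimum p-value by phenotype permutation
#'
#' The gene statistic is the most significant single-SNP allelic
#' chi-squared p-value over the gene's SNPs; its significance is obtained
#' by permuting disease status among individuals and recomputing, which
#' accounts for LD between the SNPs. Permutations escalate from
#' \code{nPermBase} to \code{10 * nPermBase} when the first-stage p-value
#' falls below 0.01. Genes without a single SNP at p < 0.05 are screened
#' out and return \code{NA} with \code{analysed = FALSE}.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param geneSnps character vector of the gene's SNP ids.
#' @param nPermBase first-stage permutation count (default 1000).
#' @param seed integer seed.
#' @param screenP single-SNP screening threshold (default 0.05).
#' @return list with \code{best_snp_id}, \code{best_p},
#'   \code{corrected_min_p}, \code{n_perm_used}, \code{analysed}.
#' @export
geneMinpCorrected <- function(dataset, geneSnps, nPermBase = 1000,
                              seed = 1L, screenP = 0.05) {
  stopifnot(is(dataset, "GenotypeDataset"), length(geneSnps) >= 1)
  idx <- match(geneSnps, dataset@snpInfo$snp_id)
  if (anyNA(idx)) stop("unknown SNP id(s): ",
                       paste(geneSnps[is.na(idx)], collapse = ", "))
  stats_obs <- computeSummaryStats(dataset)[idx, , drop = FALSE]
  best <- which.min(stats_obs$p_value)
  best_p <- stats_obs$p_value[best]
  if (best_p >= screenP)
    return(list(best_snp_id = stats_obs$snp_id[best], best_p = best_p,
                corrected_min_p = NA_real_, n_perm_used = 0L,
                analysed = FALSE))
  D <- dataset@dosages[, idx, drop = FALSE]
  obs_max <- max(stats_obs$chi2)
  run <- function(B) {
    Y <- .permIndicator(dataset, B)
    perm_max <- apply(.chi2Perm(D, Y), 2L, max)
    (1 + sum(perm_max >= obs_max)) / (B + 1)
  }
  set.seed(seed)
  p <- run(nPermBase)
  n_used <- nPermBase
  if (p < 0.01) {
    set.seed(seed + 1L)
    n_used <- 10L * nPermBase
    p <- run(n_used)
  }
  list(best_snp_id = stats_obs$snp_id[best], best_p = best_p,
       corrected_min_p = p, n_perm_used = as.integer(n_used),
       analysed = TRUE)
}

#' Set-based test of the average allelic chi-squared
#'
#' The statistic is the mean 1-df allelic chi-squared over the given
#' SNPs; its null distribution comes from permuting disease status among
#' individuals, which is robust to LD within and between genes and to
#' SNPs belonging to several genes. Add-one empirical p-value.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param snpIds SNPs of the gene or gene set.
#' @param nPerm permutation count (default 1000).
#' @param seed integer seed.
#' @return the permutation p-value.
#' @export
setAverageChi2P <- function(dataset, snpIds, nPerm = 1000, seed = 1L) {
  stopifnot(is(dataset, "GenotypeDataset"), length(snpIds) >= 1)
  idx <- match(snpIds, dataset@snpInfo$snp_id)
  if (anyNA(idx)) stop("unknown SNP id(s): ",
                       paste(snpIds[is.na(idx)], collapse = ", "))
  stats_obs <- computeSummaryStats(dataset)[idx, , drop = FALSE]
  if (all(stats_obs$monomorphic))
    stop("all SNPs in the set are monomorphic")
  obs_mean <- mean(stats_obs$chi2)
  D <- dataset@dosages[, idx, drop = FALSE]
  set.seed(seed)
  Y <- .permIndicator(dataset, nPerm)
  perm_mean <- colMeans(.chi2Perm(D, Y))
  (1 + sum(perm_mean >= obs_mean)) / (nPerm + 1)
}

#' Weighted running-sum enrichment score
#'
#' Genes are ranked by decreasing score; walking down the ranking, the
#' running sum rises by \code{score / sum(in-set scores)} at in-set genes
#' and falls by \code{1 / (#genes - set size)} at out-of-set genes
#' (weight exponent 1). The enrichment score is the maximum of the
#' running sum.
#'
#' @param scores numeric vector of gene scores (larger = more
#'   associated), named by gene id.
#' @param inSet logical vector parallel to \code{scores}.
#' @return the enrichment score.
#' @export
gseaEnrichmentScore <- function(scores, inSet) {
  stopifnot(length(scores) == length(inSet), any(inSet), !all(inSet))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; m <- inSet[ord]
  nr <- sum(s[m])
  if (nr <= 0) return(0)
  step <- ifelse(m, s / nr, -1 / sum(!m))
  max(cumsum(step))
}

#' Rank-based gene-set enrichment of gene-wide statistics
#'
#' Ranks all genes by decreasing \code{-log} Simes p-value and asks
#' whether a set's genes sit higher in the ranking than chance allows,
#' via the weighted running-sum enrichment score. Two null modes:
#' \code{"summary"} permutes gene labels (for studies where only summary
#' statistics exist); \code{"genotype"} permutes disease status and
#' recomputes every gene's Simes statistic from the genotypes, which
#' preserves LD and gene size. Sets with fewer than \code{minGenes}
#' scored genes are skipped with a warning.
#'
#' @param geneStats named numeric vector of per-gene Simes p-values
#'   (see [simesP()]); names are gene ids.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param nPerm permutation count.
#' @param mode \code{"summary"} or \code{"genotype"}.
#' @param dataset \linkS4class{GenotypeDataset}, required in genotype
#'   mode.
#' @param map \linkS4class{SnpGeneMap}, required in genotype mode (gene
#'   to SNP assignment for recomputing gene statistics).
#' @param seed integer seed.
#' @param minGenes minimum scored genes per set (default 3).
#' @return data.frame with columns \code{set_id}, \code{es},
#'   \code{empirical_p}, \code{mode}.
#' @export
gsea <- function(geneStats, sets, nPerm = 1000,
                 mode = c("summary", "genotype"),
                 dataset = NULL, map = NULL, seed = 1L, minGenes = 3) {
  mode <- match.arg(mode)
  stopifnot(is(sets, "GeneSetCollection"), length(geneStats) >= 2)
  scores <- -log(geneStats)
  genes <- names(geneStats)
  memb <- lapply(sets@genes, function(g) genes %in% g)
  n_in <- vapply(memb, sum, 0L)
  skip <- n_in < minGenes | n_in == length(genes)
  if (any(skip))
    warning(sum(skip), " set(s) skipped: fewer than ", minGenes,
            " scored genes (or no out-of-set genes)")
  keep <- which(!skip)
  if (length(keep) == 0L)
    return(data.frame(set_id = character(0), es = numeric(0),
                      empirical_p = numeric(0), mode = character(0)))
  es_obs <- vapply(keep, function(i) gseaEnrichmentScore(scores, memb[[i]]), 0)
  set.seed(seed)
  exceed <- integer(length(keep))
  if (mode == "summary") {
    for (b in seq_len(nPerm)) {
      perm_scores <- scores[sample.int(length(scores))]
      for (k in seq_along(keep)) {
        es <- gseaEnrichmentScore(perm_scores, memb[[keep[k]]])
        if (es >= es_obs[k]) exceed[k] <- exceed[k] + 1L
      }
    }
  } else {
    if (is.null(dataset) || is.null(map))
      stop("genotype mode needs dataset and map")
    g2s <- map@geneToSnps[genes]
    snp_ids <- unique(unlist(g2s, use.names = FALSE))
    idx <- match(snp_ids, dataset@snpInfo$snp_id)
    if (anyNA(idx)) stop("map refers to SNPs absent from the dataset")
    D <- dataset@dosages[, idx, drop = FALSE]
    gene_rows <- lapply(g2s, function(s) match(s, snp_ids))
    block <- 100L
    done <- 0L
    while (done < nPerm) {
      B <- min(block, nPerm - done)
      Y <- .permIndicator(dataset, B)
      chi2 <- .chi2Perm(D, Y)
      P <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
      P[P <= 0] <- .Machine$double.xmin
      for (b in seq_len(B)) {
        perm_scores <- vapply(gene_rows,
                              function(rows) -log(simesP(P[rows, b])), 0)
        for (k in seq_along(keep)) {
          es <- gseaEnrichmentScore(perm_scores, memb[[keep[k]]])
          if (es >= es_obs[k]) exceed[k] <- exceed[k] + 1L
        }
      }
      done <- done + B
    }
  }
  data.frame(set_id = sets@setIds[keep], es = es_obs,
             empirical_p = (1 + exceed) / (nPerm + 1),
             mode = mode, stringsAsFactors = FALSE)
}

#' Gene-wide Simes p-values from per-SNP summary statistics
#'
#' Convenience: applies [simesP()] to each mapped gene's SNP p-values,
#' the gene-wide statistic used for GSEA ranking.
#'
#' @param snps SNP table with \code{p_value}.
#' @param map a \linkS4class{SnpGeneMap}.
#' @return named numeric vector of Simes p-values (mapped genes only).
#' @export
geneSimesStats <- function(snps, map) {
  checkSnpTable(snps)
  stopifnot(is(map, "SnpGeneMap"))
  p <- stats::setNames(snps$p_value, snps$snp_id)
  g2s <- map@geneToSnps[lengths(map@geneToSnps) > 0L]
  vapply(g2s, function(s) simesP(p[s]), 0)
}
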