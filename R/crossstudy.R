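## Replication of enriched categories in a second study and joint
## enrichment across studies. The overlap null resamples: the replication
## study's own replicate gene lists are scored over the discovery-selected
## categories, which accounts for the correlation between enrichment
## p-values of overlapping categories (a Binomial(#selected, threshold)
## tail would not).

#' Minimum cross-study null products over a category collection
#'
#' Pairs replicate r of the discovery study with replicate r of the
#' replication study and records, per pair, the minimum over categories of
#' the product of the two leave-one-out enrichment p-values. These minima
#' are the null for the multiplicity-corrected joint enrichment p-value.
#'
#' @param repP1,repP2 leave-one-out p-value matrices of the two studies
#'   (from [leaveOneOutP()]); columns are matched by name, rows paired by
#'   index (the shorter study truncates the pairing).
#' @return numeric vector of per-pair minimum products.
#' @export
pairNullMinProducts <- function(repP1, repP2) {
  common <- intersect(colnames(repP1), colnames(repP2))
  if (length(common) == 0L) stop("no categories shared between studies")
  B <- min(nrow(repP1), nrow(repP2))
  prod <- repP1[seq_len(B), common, drop = FALSE] *
    repP2[seq_len(B), common, drop = FALSE]
  apply(prod, 1L, min)
}

#' Multiplicity-corrected joint enrichment p-value
#'
#' The probability of observing by chance at least one category, among
#' the entire collection tested, whose product of the two studies'
#' enrichment p-values is at least as small as the observed product:
#' \code{(1 + #\{pairs with min product <= p1 * p2\}) / (nPairs + 1)}.
#'
#' @param p1,p2 enrichment p-values of a category in the two studies
#'   (vectorized).
#' @param nullMinProducts per-pair minimum products from
#'   [pairNullMinProducts()].
#' @return numeric vector of joint p-values.
#' @export
jointEnrichmentP <- function(p1, p2, nullMinProducts) {
  n <- length(nullMinProducts)
  stopifnot(n >= 1, length(p1) == length(p2))
  obs <- p1 * p2
  vapply(obs, function(x) (1 + sum(nullMinProducts <= x)) / (n + 1), 0)
}

#' Cross-study replication and joint enrichment
#'
#' Restricts attention to the categories enriched in the discovery study
#' (enrichment p below \code{selectThreshold} with at least two signals),
#' counts how many are also enriched in the replication study, and tests
#' that overlap count against the replication study's own replicate
#' lists scored over the same selected categories. Also reports, for
#' every selected category, the per-study p-values, their product, and
#' the multiplicity-corrected joint enrichment p-value over all
#' categories tested in both studies.
#'
#' @param discovery,replication results of [runAligator()] on the two
#'   studies (same category collection).
#' @param selectThreshold discovery enrichment threshold (default 0.05).
#' @param replicationThreshold replication enrichment threshold
#'   (default 0.05).
#' @return list with \code{selected_set_ids}, \code{overlap_count},
#'   \code{overlap_p}, and \code{per_set} (data.frame: set_id, p1, p2,
#'   n_sig1, n_sig2, joint_product, joint_p).
#' @export
crossStudyAnalysis <- function(discovery, replication,
                               selectThreshold = 0.05,
                               replicationThreshold = 0.05) {
  d <- discovery$enrichment
  r <- replication$enrichment
  selected <- d$set_id[d$p_enrich < selectThreshold & d$n_sig >= 2L]
  selected <- intersect(selected, r$set_id)
  if (length(selected) == 0L) {
    warning("no discovery-enriched categories to replicate")
    return(list(selected_set_ids = character(0), overlap_count = 0L,
                overlap_p = 1,
                per_set = data.frame(set_id = character(0), p1 = numeric(0),
                                     p2 = numeric(0), n_sig1 = integer(0),
                                     n_sig2 = integer(0),
                                     joint_product = numeric(0),
                                     joint_p = numeric(0))))
  }
  ri <- match(selected, r$set_id)
  hit2 <- r$p_enrich[ri] < replicationThreshold & r$n_sig[ri] >= 2L
  overlap_count <- sum(hit2)
  ## null: the replication study's replicate lists over the same categories
  repP <- replication$repP[, selected, drop = FALSE]
  H <- replication$H[, selected, drop = FALSE]
  rep_counts <- rowSums(repP < replicationThreshold & H >= 2L)
  overlap_p <- (1 + sum(rep_counts >= overlap_count)) / (nrow(repP) + 1)
  nullmin <- pairNullMinProducts(discovery$repP, replication$repP)
  di <- match(selected, d$set_id)
  p1 <- d$p_enrich[di]; p2 <- r$p_enrich[ri]
  per_set <- data.frame(
    set_id = selected, p1 = p1, p2 = p2,
    n_sig1 = d$n_sig[di], n_sig2 = r$n_sig[ri],
    joint_product = p1 * p2,
    joint_p = jointEnrichmentP(p1, p2, nullmin),
    stringsAsFactors = FALSE
  )
  per_set <- per_set[order(per_set$joint_product), , drop = FALSE]
  list(selected_set_ids = selected, overlap_count = as.integer(overlap_count),
       overlap_p = overlap_p, per_set = per_set)
}
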