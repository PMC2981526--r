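## Effective number of independent SNPs under LD, and the binomial test
## for an excess of significant SNPs at a ladder of thresholds. The
## effective count uses a sliding-window max-r-squared form: the first SNP
## of each chromosome contributes 1, and every later SNP contributes
## sqrt(1 - max r2) over its preceding window, so independent SNPs count
## fully and perfectly correlated SNPs not at all.

#' Estimate the effective number of independent SNPs
#'
#' SNPs are ordered by position within chromosome; SNP i contributes
#' \eqn{\kappa_i = \sqrt{1 - \max_j r^2_{ij}}} where j ranges over the
#' preceding \code{windowSnps} SNPs on the same chromosome (the first SNP
#' of each chromosome contributes 1). The result lies in [1, M]; all-zero
#' r-squared gives M, all-one gives 1. Pairs missing from \code{ld} are
#' treated as independent (r2 = 0) and counted in a warning.
#'
#' @param snps SNP table.
#' @param ld an \linkS4class{LdInfo}; pass an empty one for independent
#'   SNPs.
#' @param windowSnps number of preceding SNPs examined per SNP
#'   (default 50).
#' @return single numeric, the effective number of independent tests.
#' @export
estimateEffectiveTests <- function(snps, ld, windowSnps = 50) {
  checkSnpTable(snps)
  stopifnot(is(ld, "LdInfo"), windowSnps >= 1)
  if (nrow(snps) == 0L) return(0)
  ord <- order(snps$chrom, snps$pos_bp)
  id <- snps$snp_id[ord]
  chrom <- snps$chrom[ord]
  p <- ld@pairs
  if (nrow(p) == 0L) return(as.numeric(nrow(snps)))
  keys <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_len(nrow(p))) {
    a <- p$snp_a[k]; b <- p$snp_b[k]
    key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    assign(key, p$r2[k], envir = keys)
  }
  keff <- 0
  n_missing <- 0L
  for (i in seq_along(id)) {
    lo <- max(1L, i - as.integer(windowSnps))
    js <- seq(lo, i - 1L)
    js <- js[js >= 1L & chrom[js] == chrom[i]]
    if (i == 1L || length(js) == 0L) {
      keff <- keff + 1
      next
    }
    max_r2 <- 0
    for (j in js) {
      a <- id[j]; b <- id[i]
      key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
      r2 <- keys[[key]]
      if (is.null(r2)) {
        n_missing <- n_missing + 1L
        r2 <- 0
      }
      if (r2 > max_r2) max_r2 <- r2
    }
    keff <- keff + sqrt(max(0, 1 - max_r2))
  }
  if (n_missing > 0L)
    warning(n_missing,
            " in-window SNP pair(s) missing from the LD table; treated as r2 = 0")
  keff
}

#' Upper-tail binomial test for an excess of significant SNPs
#'
#' Under no excess association, the number of independent SNPs significant
#' at level \code{alpha} follows Binomial(N, alpha) with N the effective
#' number of independent tests. Returns the exact upper tail
#' \eqn{P(X \ge \lceil observed \rceil)} with X ~ Binomial(round(nEff),
#' alpha); a non-integer observed count is ceiled, which is conservative.
#'
#' @param nEff effective number of independent SNPs (genome-wide).
#' @param alpha significance level in (0, 1).
#' @param observedEff estimated number of independent significant SNPs;
#'   must not exceed \code{nEff}.
#' @return the upper-tail p-value.
#' @export
binomialExcessP <- function(nEff, alpha, observedEff) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stopifnot(observedEff >= 0, nEff >= observedEff)
  k <- ceiling(observedEff)
  if (k == 0) return(1)
  n <- round(nEff)
  stats::pbinom(k - 1, size = n, prob = alpha, lower.tail = FALSE)
}

#' Excess-of-significant-SNPs table over a threshold ladder
#'
#' One row per threshold: the raw count of SNPs with p below the
#' threshold, the LD-adjusted (effective) count among them, the expected
#' effective count (genome-wide effective N times the threshold), the
#' binomial upper-tail p-value, and the estimated/expected ratio reported
#' to two decimals.
#'
#' @param snps SNP table.
#' @param ld an \linkS4class{LdInfo}.
#' @param alphas numeric vector of thresholds, strictly monotone.
#' @param windowSnps window passed to [estimateEffectiveTests()].
#' @return data.frame with columns \code{alpha}, \code{n_sig_raw},
#'   \code{keff_sig}, \code{expected}, \code{binom_p}, \code{ratio}.
#' @export
buildExcessTable <- function(snps, ld,
                             alphas = c(1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05),
                             windowSnps = 50) {
  checkSnpTable(snps)
  stopifnot(length(alphas) >= 1, all(alphas > 0), all(alphas < 1))
  if (length(alphas) > 1) {
    dd <- diff(alphas)
    if (!(all(dd > 0) || all(dd < 0)))
      stop("alphas must be strictly increasing or strictly decreasing")
  }
  keff_genome <- estimateEffectiveTests(snps, ld, windowSnps)
  rows <- lapply(alphas, function(a) {
    sub <- snps[snps$p_value < a, , drop = FALSE]
    n_raw <- nrow(sub)
    expected <- keff_genome * a
    if (n_raw == 0L) {
      return(data.frame(alpha = a, n_sig_raw = 0L, keff_sig = 0,
                        expected = expected, binom_p = 1,
                        ratio = round(0 / expected, 2)))
    }
    keff_sig <- estimateEffectiveTests(sub, ld, windowSnps)
    data.frame(alpha = a, n_sig_raw = n_raw, keff_sig = keff_sig,
               expected = expected,
               binom_p = binomialExcessP(keff_genome, a, keff_sig),
               ratio = excessRatio(keff_sig, expected))
  })
  do.call(rbind, rows)
}

#' Estimated/expected ratio, reported to two decimals
#'
#' The ratio of the LD-adjusted count of significant SNPs to its binomial
#' expectation, rounded to two decimals as reported in excess tables.
#'
#' @param estimated effective number of significant SNPs.
#' @param expected expected effective number at the same threshold.
#' @return numeric vector of two-decimal ratios.
#' @export
excessRatio <- function(estimated, expected) {
  stopifnot(all(expected > 0))
  round(estimated / expected, 2)
}
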