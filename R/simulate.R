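## Case-control GWAS simulator. Genotypes come from a latent first-order
## autoregressive Gaussian per gene block, thresholded at quantiles that
## give each SNP its minor-allele frequency (two independent haplotypes per
## individual, so Hardy-Weinberg holds and adjacent-SNP correlation is
## controlled in closed form by the latent autocorrelation). Disease status
## follows a logistic model over planted causal SNPs; cases and controls
## are collected by rejection from the population simulator, preserving the
## retrospective design the allelic chi-squared test assumes.

#' Build a simulation configuration
#'
#' Collects and validates the parameters of the synthetic GWAS generator.
#' Defaults describe the study conditions used throughout the package's
#' calibration and power checks: 2000 cases and 2000 controls, 200 genes
#' of highly variable SNP content on one synthetic chromosome, block LD
#' with latent autocorrelation 0.8, and 50 gene sets of 10 genes.
#'
#' @param nCases,nControls numbers of cases and controls to collect.
#' @param nGenes number of genes laid along one synthetic chromosome.
#' @param snpsPerGene integer vector \code{c(min, max)}; each gene draws
#'   its SNP count uniformly from this range.
#' @param geneLengthBp gene body length in base pairs.
#' @param intergenicBp gap between consecutive gene bodies; the default
#'   exceeds twice the 20 kb assignment window so non-overlapping genes
#'   never share SNPs.
#' @param ldRho latent autocorrelation between adjacent SNPs within a gene
#'   block, in [0, 1).
#' @param mafRange minor-allele frequency range \code{c(low, high)} within
#'   (0, 0.5]; each SNP draws its MAF uniformly from this range.
#' @param nSets,genesPerSet number of gene sets and genes per set; sets
#'   sample their members uniformly from all genes.
#' @param plantedSets character vector of set ids (\code{"SET01"}, ...)
#'   that receive causal SNPs.
#' @param causalFraction fraction of a planted set's genes carrying one
#'   causal SNP.
#' @param causalOr per-allele odds ratio at causal SNPs; 1 gives a null
#'   dataset.
#' @param prevalence baseline disease prevalence of the population
#'   simulator (log-odds are centred so the realised prevalence stays near
#'   this value under planted effects).
#' @param overlapFrac fraction of consecutive gene pairs laid out so the
#'   downstream gene overlaps the upstream gene's tail, making boundary
#'   SNPs fall within both gene bodies (adjacent-paralog and HLA-like
#'   sharing).
#' @param seed integer seed; the same configuration and seed reproduce the
#'   dataset exactly.
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nCases = 2000, nControls = 2000,
                             nGenes = 200, snpsPerGene = c(2, 25),
                             geneLengthBp = 50000, intergenicBp = 50000,
                             ldRho = 0.8, mafRange = c(0.05, 0.5),
                             nSets = 50, genesPerSet = 10,
                             plantedSets = character(),
                             causalFraction = 0.5, causalOr = 1.0,
                             prevalence = 0.1, overlapFrac = 0,
                             seed = 1L) {
  cfg <- list(nCases = as.integer(nCases), nControls = as.integer(nControls),
              nGenes = as.integer(nGenes),
              snpsPerGene = as.integer(snpsPerGene),
              geneLengthBp = as.integer(geneLengthBp),
              intergenicBp = as.integer(intergenicBp),
              ldRho = ldRho, mafRange = mafRange,
              nSets = as.integer(nSets), genesPerSet = as.integer(genesPerSet),
              plantedSets = as.character(plantedSets),
              causalFraction = causalFraction, causalOr = causalOr,
              prevalence = prevalence, overlapFrac = overlapFrac,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(nCases >= 1, nControls >= 1, nGenes >= 1,
              length(snpsPerGene) == 2L, snpsPerGene[1] >= 1,
              snpsPerGene[1] <= snpsPerGene[2],
              geneLengthBp >= 1, intergenicBp >= 0,
              ldRho >= 0, ldRho < 1,
              length(mafRange) == 2L, mafRange[1] > 0,
              mafRange[1] <= mafRange[2], mafRange[2] <= 0.5,
              nSets >= 0, genesPerSet >= 1,
              causalFraction >= 0, causalFraction <= 1, causalOr > 0,
              prevalence > 0, prevalence < 1,
              overlapFrac >= 0, overlapFrac <= 1)
  })
  class(cfg) <- "SimulationConfig"
  cfg
}

## gene layout on one synthetic chromosome; overlapping pairs shift the
## downstream gene's start into the upstream gene's tail
.layoutGenes <- function(cfg) {
  n <- cfg$nGenes
  overlap_pair <- rep(FALSE, n)
  if (cfg$overlapFrac > 0 && n > 1) {
    n_over <- floor(cfg$overlapFrac * (n - 1))
    if (n_over > 0) {
      cand <- seq(2L, n)
      overlap_pair[cand[sample.int(length(cand), n_over)]] <- TRUE
    }
  }
  start <- integer(n); end <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    if (i > 1 && overlap_pair[i]) {
      start[i] <- end[i - 1] - as.integer(cfg$geneLengthBp %/% 2) + 1L
    } else {
      start[i] <- pos
    }
    end[i] <- start[i] + cfg$geneLengthBp - 1L
    pos <- end[i] + cfg$intergenicBp + 1L
  }
  data.frame(gene_id = sprintf("G%04d", seq_len(n)), chrom = "1",
             start_bp = start, end_bp = end, stringsAsFactors = FALSE)
}

## place each gene's own SNPs in the part of its body not covered by the
## previous gene, so overlapping genes share the upstream tail SNPs
## without coincident positions
.placeSnps <- function(cfg, genes) {
  rng <- seq(cfg$snpsPerGene[1], cfg$snpsPerGene[2])
  counts <- rng[sample.int(length(rng), cfg$nGenes, replace = TRUE)]
  pos <- vector("list", cfg$nGenes)
  prev_end <- 0L
  for (i in seq_len(cfg$nGenes)) {
    lo <- max(genes$start_bp[i], prev_end + 1L)
    hi <- genes$end_bp[i]
    k <- counts[i]
    pos[[i]] <- as.integer(round(seq(lo, hi, length.out = k + 2L)[2:(k + 1L)]))
    prev_end <- genes$end_bp[i]
  }
  data.frame(
    snp_id = sprintf("rs%06d", seq_len(sum(counts))),
    chrom = "1", pos_bp = unlist(pos),
    block = rep(seq_len(cfg$nGenes), counts),
    stringsAsFactors = FALSE
  )
}

## two latent AR(1) haplotypes per individual per block, thresholded at
## qnorm(maf)
.drawDosages <- function(n, block_sizes, rho, thresholds) {
  m <- sum(block_sizes)
  d <- matrix(0L, n, m)
  for (hap in 1:2) {
    col <- 0L
    for (k in block_sizes) {
      z <- matrix(0, n, k)
      z[, 1] <- stats::rnorm(n)
      if (k > 1) {
        sd_innov <- sqrt(1 - rho^2)
        for (j in 2:k)
          z[, j] <- rho * z[, j - 1] + sd_innov * stats::rnorm(n)
      }
      th <- thresholds[(col + 1L):(col + k)]
      d[, (col + 1L):(col + k)] <-
        d[, (col + 1L):(col + k)] + (z < rep(th, each = n))
      col <- col + k
    }
  }
  d
}

#' Simulate a case-control GWAS dataset with planted pathway effects
#'
#' Generates individual-level genotypes with block LD, gene models of
#' variable SNP content (optionally overlapping so adjacent genes share
#' SNPs), gene sets, and case-control status from a logistic model whose
#' causal SNPs are concentrated in the planted sets. Cases and controls
#' are accumulated by rejection sampling until the requested counts are
#' reached; a pathological configuration that cannot reach the case quota
#' raises an error after a bounded number of draws.
#'
#' @param cfg a configuration from [simulationConfig()].
#' @return list with elements \code{dataset}
#'   (\linkS4class{GenotypeDataset}), \code{genes} (gene table),
#'   \code{sets} (\linkS4class{GeneSetCollection}) and \code{truth} (list
#'   with \code{causal_snp_ids}, \code{planted_set_ids}, \code{snp_or} —
#'   the per-SNP true odds ratios).
#' @export
simulateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  genes <- .layoutGenes(cfg)
  snps <- .placeSnps(cfg, genes)
  m <- nrow(snps)
  maf <- stats::runif(m, cfg$mafRange[1], cfg$mafRange[2])
  thresholds <- stats::qnorm(maf)
  block_sizes <- as.integer(table(factor(snps$block,
                                         levels = seq_len(cfg$nGenes))))

  ## gene sets
  if (cfg$nSets > 0) {
    gps <- min(cfg$genesPerSet, cfg$nGenes)
    members <- lapply(seq_len(cfg$nSets),
                      function(i) sort(sample(genes$gene_id, gps)))
    sets <- new("GeneSetCollection",
                setIds = sprintf("SET%02d", seq_len(cfg$nSets)),
                setNames = sprintf("synthetic set %d", seq_len(cfg$nSets)),
                source = rep("custom", cfg$nSets),
                genes = members)
  } else {
    sets <- new("GeneSetCollection", setIds = character(),
                setNames = character(), source = character(),
                genes = list())
  }

  ## causal SNPs: middle SNP of a causalFraction of each planted set's genes
  planted <- intersect(cfg$plantedSets, sets@setIds)
  if (length(planted) < length(cfg$plantedSets))
    stop("unknown planted set id(s): ",
         paste(setdiff(cfg$plantedSets, sets@setIds), collapse = ", "))
  causal_idx <- integer(0)
  if (length(planted) && cfg$causalOr != 1 && cfg$causalFraction > 0) {
    causal_genes <- unique(unlist(lapply(planted, function(s) {
      g <- sets@genes[[match(s, sets@setIds)]]
      n_causal <- max(1L, round(cfg$causalFraction * length(g)))
      sample(g, n_causal)
    })))
    gi <- match(causal_genes, genes$gene_id)
    causal_idx <- vapply(gi, function(i) {
      in_block <- which(snps$block == i)
      in_block[ceiling(length(in_block) / 2)]
    }, 0L)
  }
  snp_or <- rep(1, m)
  snp_or[causal_idx] <- cfg$causalOr
  beta <- log(snp_or[causal_idx])
  ## centre the log-odds at the expected causal dosage so realised
  ## prevalence stays near the configured baseline
  baseline <- stats::qlogis(cfg$prevalence) -
    if (length(causal_idx)) sum(beta * 2 * maf[causal_idx]) else 0

  need_case <- cfg$nCases; need_ctrl <- cfg$nControls
  batch <- max(1000L, need_case + need_ctrl)
  max_draws <- 200L * (need_case + need_ctrl)
  drawn <- 0L
  kept <- list(); pheno <- list()
  while ((need_case > 0 || need_ctrl > 0) && drawn < max_draws) {
    d <- .drawDosages(batch, block_sizes, cfg$ldRho, thresholds)
    drawn <- drawn + batch
    eta <- baseline +
      if (length(causal_idx)) drop(d[, causal_idx, drop = FALSE] %*% beta) else 0
    y <- stats::rbinom(batch, 1L, stats::plogis(eta))
    take_case <- which(y == 1L)[seq_len(min(need_case, sum(y == 1L)))]
    take_ctrl <- which(y == 0L)[seq_len(min(need_ctrl, sum(y == 0L)))]
    take <- c(take_case, take_ctrl)
    if (length(take)) {
      kept[[length(kept) + 1L]] <- d[take, , drop = FALSE]
      pheno[[length(pheno) + 1L]] <- y[take]
      need_case <- need_case - length(take_case)
      need_ctrl <- need_ctrl - length(take_ctrl)
    }
  }
  if (need_case > 0 || need_ctrl > 0)
    stop("could not reach the requested case/control counts within ",
         max_draws, " population draws; check causalOr and prevalence")
  dos <- do.call(rbind, kept)
  y <- unlist(pheno)
  storage.mode(dos) <- "integer"
  dataset <- new("GenotypeDataset",
                 dosages = dos,
                 phenotype = factor(ifelse(y == 1L, "case", "control"),
                                    levels = c("control", "case")),
                 individualIds = sprintf("ind%05d", seq_along(y)),
                 snpInfo = snps[, c("snp_id", "chrom", "pos_bp")])
  list(dataset = dataset, genes = genes, sets = sets,
       truth = list(causal_snp_ids = snps$snp_id[causal_idx],
                    planted_set_ids = planted,
                    snp_or = stats::setNames(snp_or, snps$snp_id)))
}

#' Per-SNP allelic chi-squared summary statistics
#'
#' For each SNP, the classical 1-df allelic test on the 2x2 table of
#' allele counts (2 per individual) by case-control status:
#' \eqn{\chi^2 = n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}, without
#' continuity correction. Missing dosages are excluded per SNP.
#' Monomorphic SNPs get chi-squared 0, p-value 1, and are flagged.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @return SNP table (see [checkSnpTable()]) with columns \code{chi2},
#'   \code{p_value} and logical \code{monomorphic}.
#' @export
computeSummaryStats <- function(dataset) {
  stopifnot(is(dataset, "GenotypeDataset"))
  d <- dataset@dosages
  is_case <- dataset@phenotype == "case"
  obs <- !is.na(d)
  d0 <- d; d0[!obs] <- 0L
  a <- colSums(d0[is_case, , drop = FALSE])          # minor alleles, cases
  case_n <- colSums(obs[is_case, , drop = FALSE])
  b <- 2 * case_n - a                                 # major alleles, cases
  c_ <- colSums(d0[!is_case, , drop = FALSE])
  ctrl_n <- colSums(obs[!is_case, , drop = FALSE])
  dd <- 2 * ctrl_n - c_
  n <- a + b + c_ + dd
  num <- n * (a * dd - b * c_)^2
  den <- (a + b) * (c_ + dd) * (a + c_) * (b + dd)
  chi2 <- ifelse(den > 0, num / den, 0)
  mono <- (a + c_ == 0) | (b + dd == 0)
  chi2[mono] <- 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p[mono] <- 1
  p <- pmin(p, 1)
  p[p <= 0] <- .Machine$double.xmin  # keep within the (0, 1] contract
  out <- dataset@snpInfo
  out$chi2 <- as.numeric(chi2)
  out$p_value <- p
  out$monomorphic <- as.logical(mono)
  checkSnpTable(out)
  out
}

#' Estimate pairwise LD from genotypes
#'
#' Squared Pearson correlation between dosages of SNP pairs within a
#' sliding window of neighbouring SNPs (position-ordered within
#' chromosome). Intended both for the effective-number-of-tests
#' calculation and for building \linkS4class{LdInfo} inputs from simulated
#' data.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param windowSnps number of preceding SNPs considered per SNP.
#' @param minR2 pairs with r-squared below this value are omitted from the
#'   table (0 keeps everything).
#' @return an \linkS4class{LdInfo}.
#' @export
ldFromGenotypes <- function(dataset, windowSnps = 50, minR2 = 0) {
  stopifnot(is(dataset, "GenotypeDataset"), windowSnps >= 1)
  info <- dataset@snpInfo
  ord <- order(info$chrom, info$pos_bp)
  d <- dataset@dosages[, ord, drop = FALSE]
  info <- info[ord, , drop = FALSE]
  m <- ncol(d)
  z <- scale(d)
  z[is.na(z)] <- 0
  n1 <- nrow(d) - 1L
  res_a <- character(0); res_b <- character(0); res_r2 <- numeric(0)
  for (off in seq_len(min(windowSnps, m - 1L))) {
    i <- seq_len(m - off)
    j <- i + off
    same <- info$chrom[i] == info$chrom[j]
    if (!any(same)) next
    r <- colSums(z[, i[same], drop = FALSE] * z[, j[same], drop = FALSE]) / n1
    r2 <- pmin(r^2, 1)
    keep <- r2 >= minR2 & !is.na(r2)
    res_a <- c(res_a, info$snp_id[i[same]][keep])
    res_b <- c(res_b, info$snp_id[j[same]][keep])
    res_r2 <- c(res_r2, r2[keep])
  }
  new("LdInfo", pairs = data.frame(snp_a = res_a, snp_b = res_b,
                                   r2 = res_r2, stringsAsFactors = FALSE))
}
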