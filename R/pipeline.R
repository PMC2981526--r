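## Orchestration: a single entry point that reads a flat key=value
## configuration, runs the stages in dependency order (map -> excess ->
## enrichment -> report), writes all result tables as #-headed TSVs, and
## leaves a run manifest (config snapshot, seed, input digests, package
## version, timing) so a run can be reproduced byte-for-byte.

.known_config_keys <- c(
  "assoc.path", "genes.path", "gmt.path", "ld.path",
  "map.window_bp", "map.exclude", "map.keep",
  "excess.alphas", "excess.window_snps",
  "aligator.alpha_gene", "aligator.replicates", "aligator.min_genes",
  "seed"
)

#' Read a flat key=value configuration file
#'
#' One \code{key = value} pair per line; blank lines and \code{#}
#' comments ignored. Unknown keys are errors, so a misspelled threshold
#' cannot silently fall back to a default.
#'
#' @param path configuration file.
#' @return named character vector of settings.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad))
    stop("config line not of the form key = value: '", lines[bad[1]], "'")
  keys <- trimws(vapply(kv, `[[`, "", 2L))
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  unknown <- setdiff(keys, .known_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicated configuration key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  stats::setNames(vals, keys)
}

.cfg_get <- function(cfg, key, default = NULL, required = FALSE) {
  if (key %in% names(cfg)) return(cfg[[key]])
  if (required)
    stop("configuration error: required key '", key, "' is missing")
  default
}

#' Run the full pipeline from a configuration file
#'
#' Stages, in dependency order: read inputs; map SNPs to genes (with
#' optional region exclusion); excess-of-significant-SNPs table;
#' resampling enrichment with study-wide correction and the
#' excess-of-enriched-categories summary; report. Every stage's table is
#' written to \code{outDir} as a #-headed TSV, and exactly one manifest
#' (\code{manifest.json}) records the configuration snapshot, seed, input
#' digests, package version and wall-clock bounds.
#'
#' @param config path to a flat key=value configuration file (see
#'   [readPipelineConfig()]); required keys \code{assoc.path},
#'   \code{genes.path}, \code{gmt.path}.
#' @param outDir output directory, created if absent.
#' @param seed integer seed; overrides the config's \code{seed}; when
#'   neither is given one is generated and logged in the manifest.
#' @return invisibly, a list with the stage results (\code{map},
#'   \code{excess}, \code{aligator}) and the manifest.
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
  t0 <- Sys.time()
  cfg <- readPipelineConfig(config)
  assoc_path <- .cfg_get(cfg, "assoc.path", required = TRUE)
  genes_path <- .cfg_get(cfg, "genes.path", required = TRUE)
  gmt_path <- .cfg_get(cfg, "gmt.path", required = TRUE)
  ld_path <- .cfg_get(cfg, "ld.path")
  if (is.null(seed)) {
    seed_cfg <- .cfg_get(cfg, "seed")
    seed <- if (is.null(seed_cfg)) sample.int(.Machine$integer.max, 1L)
            else as.integer(seed_cfg)
  }
  seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  snps <- readAssoc(assoc_path)
  genes <- readGeneBed(genes_path)
  sets <- readGmt(gmt_path)
  ld <- if (is.null(ld_path)) new("LdInfo") else readLdTable(ld_path)

  exclude <- .cfg_get(cfg, "map.exclude")
  if (!is.null(exclude)) {
    parts <- regmatches(exclude, regexec("^([^:]+):([0-9]+)-([0-9]+)$",
                                         exclude))[[1]]
    if (length(parts) != 4L)
      stop("map.exclude must look like chr19:49600000-50600000")
    keep <- .cfg_get(cfg, "map.keep", default = "")
    keep <- strsplit(keep, ",", fixed = TRUE)[[1]]
    genes <- excludeRegion(genes, parts[2], as.numeric(parts[3]),
                           as.numeric(parts[4]), keep = trimws(keep))
  }

  window_bp <- as.numeric(.cfg_get(cfg, "map.window_bp", default = "20000"))
  alpha_gene <- as.numeric(.cfg_get(cfg, "aligator.alpha_gene",
                                    default = "0.001"))
  n_rep <- as.integer(.cfg_get(cfg, "aligator.replicates", default = "5000"))
  min_genes <- as.integer(.cfg_get(cfg, "aligator.min_genes", default = "3"))
  alphas <- as.numeric(strsplit(
    .cfg_get(cfg, "excess.alphas",
             default = "1e-6,1e-5,1e-4,1e-3,0.01,0.05"),
    ",", fixed = TRUE)[[1]])
  window_snps <- as.integer(.cfg_get(cfg, "excess.window_snps",
                                     default = "50"))

  map <- mapSnpsToGenes(snps, genes, window_bp)
  gene_list <- buildSignificantGeneList(map, snps, alpha_gene)
  excess <- buildExcessTable(snps, ld, alphas, window_snps)
  ali <- runAligator(snps, genes, sets, alphaGene = alpha_gene,
                     windowBp = window_bp, nReplicates = n_rep,
                     seed = seed, ld = ld, minGenes = min_genes)

  writeResultsTsv(data.frame(gene_id = gene_list@genes,
                             n_defining_snps = lengths(gene_list@definingSnps)),
                  file.path(outDir, "significant_genes.tsv"))
  writeResultsTsv(excess, file.path(outDir, "excess_snps.tsv"))
  writeResultsTsv(ali$enrichment, file.path(outDir, "enrichment.tsv"))
  writeResultsTsv(ali$summary, file.path(outDir, "enrichment_summary.tsv"))
  mapping_df <- data.frame(
    snp_id = rep(names(map@snpToGenes), lengths(map@snpToGenes)),
    gene_id = unlist(map@snpToGenes, use.names = FALSE))
  writeResultsTsv(mapping_df, file.path(outDir, "snp_gene_map.tsv"))

  inputs <- c(assoc = assoc_path, genes = genes_path, gmt = gmt_path)
  if (!is.null(ld_path)) inputs <- c(inputs, ld = ld_path)
  manifest <- list(
    subcommand = "pipeline",
    config = as.list(cfg),
    seed = seed,
    input_digests = as.list(tools::md5sum(inputs)),
    package_version = as.character(utils::packageVersion("aligator")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(map = map, sigList = gene_list, excess = excess,
                 aligator = ali, manifest = manifest))
}
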