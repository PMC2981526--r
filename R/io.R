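## Readers and writers for the delimited formats the pipeline consumes:
## association tables (PLINK-style), gene models (BED4), gene sets (GMT),
## LD pair tables and result tables. Internal coordinates are 1-based
## inclusive; BED's half-open 0-based convention is converted at the
## boundary. Chromosome names are normalized by stripping a leading "chr".

#' Normalize chromosome names
#'
#' Strips a leading \code{"chr"} (case-insensitive) so that mixed-dialect
#' inputs ("chr1" vs "1") compare equal.
#'
#' @param chrom character vector.
#' @return character vector of normalized names.
#' @export
normalizeChrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

#' Validate a SNP association table
#'
#' Checks the data.frame contract used throughout the package for per-SNP
#' association records: columns \code{snp_id}, \code{chrom}, \code{pos_bp}
#' (1-based, positive), \code{p_value} in (0, 1], optional \code{chi2}.
#'
#' @param snps data.frame of SNP records.
#' @return the table, invisibly, after validation.
#' @export
checkSnpTable <- function(snps) {
  stopifnot(is.data.frame(snps))
  need <- c("snp_id", "chrom", "pos_bp", "p_value")
  miss <- setdiff(need, names(snps))
  if (length(miss))
    stop("SNP table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(snps$snp_id))
    stop("SNP ids must be unique within a study")
  if (nrow(snps)) {
    if (any(!is.finite(snps$pos_bp)) || any(snps$pos_bp < 1))
      stop("pos_bp must be a positive 1-based coordinate")
    if (any(!is.finite(snps$p_value)) ||
        any(snps$p_value <= 0 | snps$p_value > 1))
      stop("p_value must lie in (0, 1]")
  }
  invisible(snps)
}

#' Validate a gene model table
#'
#' Columns \code{gene_id} (unique), \code{chrom}, \code{start_bp},
#' \code{end_bp} with \code{start_bp <= end_bp}, 1-based inclusive.
#'
#' @param genes data.frame of gene records.
#' @return the table, invisibly, after validation.
#' @export
checkGeneTable <- function(genes) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "chrom", "start_bp", "end_bp")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (nrow(genes) && any(genes$start_bp > genes$end_bp))
    stop("start_bp must not exceed end_bp")
  invisible(genes)
}

#' Read a per-SNP association table
#'
#' Reads whitespace- or tab-delimited association output in the style of
#' PLINK's \code{.assoc} files. Column names are resolved through
#' \code{dialect}; the default matches PLINK headers
#' \code{SNP CHR BP P} (plus optional \code{CHISQ}). Rows whose p-value
#' falls outside (0, 1] are rejected; the number of rejected rows is
#' attached as attribute \code{"nRejected"} and reported as a warning, so
#' rows are never dropped silently.
#'
#' @param path file path.
#' @param dialect named character vector mapping internal fields
#'   \code{snp}, \code{chrom}, \code{pos}, \code{p} (optionally
#'   \code{chi2}) to column names in the file.
#' @return data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos_bp}, \code{p_value} and, when available, \code{chi2};
#'   attribute \code{nRejected} counts rejected rows.
#' @export
readAssoc <- function(path,
                      dialect = c(snp = "SNP", chrom = "CHR",
                                  pos = "BP", p = "P", chi2 = "CHISQ")) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    cols <- strsplit(sub("^#", "", first), "[ \t]+")[[1]]
    raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    names(raw) <- cols
  } else {
    raw <- utils::read.table(path, header = TRUE, comment.char = "#",
                             stringsAsFactors = FALSE, check.names = FALSE)
  }
  for (field in c("snp", "chrom", "pos", "p")) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(raw))
      stop("association file lacks required column '",
           if (is.null(col)) field else col, "' (field '", field, "')")
  }
  p_raw <- raw[[dialect[["p"]]]]
  p <- suppressWarnings(as.numeric(p_raw))
  bad_parse <- which(is.na(p) & !is.na(p_raw))
  if (length(bad_parse))
    stop("unparsable p-value at data line ", bad_parse[1],
         ": '", p_raw[bad_parse[1]], "'")
  keep <- !is.na(p) & p > 0 & p <= 1
  n_rejected <- sum(!keep)
  out <- data.frame(
    snp_id  = as.character(raw[[dialect[["snp"]]]])[keep],
    chrom   = normalizeChrom(raw[[dialect[["chrom"]]]])[keep],
    pos_bp  = as.integer(raw[[dialect[["pos"]]]])[keep],
    p_value = p[keep],
    stringsAsFactors = FALSE
  )
  chi2_col <- if (length(dialect) >= 5L) dialect[["chi2"]] else NULL
  if (!is.null(chi2_col) && !is.na(chi2_col) && chi2_col %in% names(raw))
    out$chi2 <- as.numeric(raw[[chi2_col]])[keep]
  checkSnpTable(out)
  if (n_rejected > 0L)
    warning(n_rejected, " row(s) rejected: p-value outside (0, 1]")
  attr(out, "nRejected") <- n_rejected
  out
}

#' Write a per-SNP association table
#'
#' Emits a tab-separated table with a \code{#}-prefixed header using PLINK
#' column names, the inverse of [readAssoc()] under the default dialect.
#'
#' @param snps validated SNP table (see [checkSnpTable()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAssoc <- function(snps, path) {
  checkSnpTable(snps)
  cols <- c("SNP", "CHR", "BP", "P")
  body <- data.frame(SNP = snps$snp_id, CHR = snps$chrom,
                     BP = snps$pos_bp, P = snps$p_value)
  if ("chi2" %in% names(snps)) {
    cols <- c(cols, "CHISQ")
    body$CHISQ <- snps$chi2
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED
#'
#' Accepts BED4 (chrom, start, end, name). BED's half-open 0-based
#' intervals become the package's 1-based inclusive convention
#' (\code{start_bp = start + 1}, \code{end_bp = end}).
#'
#' @param path BED file path.
#' @return validated gene table (see [checkGeneTable()]).
#' @export
readGeneBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4L)
    stop("BED file must have at least 4 columns (chrom, start, end, name)")
  start0 <- as.numeric(raw[[2]])
  end0 <- as.numeric(raw[[3]])
  bad <- which(start0 >= end0)
  if (length(bad))
    stop("BED interval with start >= end at data line ", bad[1])
  out <- data.frame(
    gene_id  = as.character(raw[[4]]),
    chrom    = normalizeChrom(raw[[1]]),
    start_bp = as.integer(start0 + 1),
    end_bp   = as.integer(end0),
    stringsAsFactors = FALSE
  )
  checkGeneTable(out)
  out
}

#' Write gene models to BED4
#'
#' Inverse of [readGeneBed()]: 1-based inclusive coordinates are converted
#' back to BED's 0-based half-open intervals.
#'
#' @param genes validated gene table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneBed <- function(genes, path) {
  checkGeneTable(genes)
  body <- data.frame(genes$chrom, genes$start_bp - 1L, genes$end_bp,
                     genes$gene_id)
  utils::write.table(body, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{set_id <TAB> description <TAB> gene1 <TAB> gene2 ...}. Duplicate
#' gene ids within a line are deduplicated; lines with no genes are
#' dropped with a warning.
#'
#' @param path GMT file path.
#' @param source source label recorded on every set (\code{"GO"},
#'   \code{"KEGG"}, \code{"MGI"} or \code{"custom"}).
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path, source = "custom") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 2 tab-separated fields")
  ids <- vapply(fields, `[[`, "", 1L)
  descs <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- lengths(genes) == 0L
  if (any(empty)) {
    warning(sum(empty), " empty set(s) dropped: ",
            paste(ids[empty], collapse = ", "))
    ids <- ids[!empty]; descs <- descs[!empty]; genes <- genes[!empty]
  }
  new("GeneSetCollection", setIds = ids, setNames = descs,
      source = rep(source, length(ids)), genes = genes)
}

#' Write gene sets to a GMT file
#'
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(sets, path) {
  stopifnot(is(sets, "GeneSetCollection"))
  lines <- vapply(seq_along(sets@setIds), function(i) {
    paste(c(sets@setIds[i], sets@setNames[i], sets@genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a pairwise LD table
#'
#' Tab-separated columns \code{snp_a}, \code{snp_b}, \code{r2} (header
#' optional, \code{#}-prefixed header accepted).
#'
#' @param path file path.
#' @param clusters optional list of character vectors of identifiers to be
#'   collapsed into single signals.
#' @return an \linkS4class{LdInfo}.
#' @export
readLdTable <- function(path, clusters = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  has_header <- startsWith(first, "#") || grepl("snp_a", first, fixed = TRUE)
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           skip = if (has_header && !startsWith(first, "#")) 1L else 0L,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("LD table needs columns snp_a, snp_b, r2")
  new("LdInfo",
      pairs = data.frame(snp_a = as.character(raw[[1]]),
                         snp_b = as.character(raw[[2]]),
                         r2 = as.numeric(raw[[3]]),
                         stringsAsFactors = FALSE),
      clusters = clusters)
}

#' Write a pairwise LD table
#'
#' @param ld an \linkS4class{LdInfo}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLdTable <- function(ld, path) {
  stopifnot(is(ld, "LdInfo"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#snp_a\tsnp_b\tr2", con)
  utils::write.table(ld@pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write genotype dosages as TSV
#'
#' One row per individual: id, phenotype, then one dosage column per SNP
#' named by snp id. Missing dosages are written as \code{NA}.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(dataset, path) {
  stopifnot(is(dataset, "GenotypeDataset"))
  body <- data.frame(individual = dataset@individualIds,
                     phenotype = as.character(dataset@phenotype),
                     dataset@dosages, check.names = FALSE,
                     stringsAsFactors = FALSE)
  names(body)[-(1:2)] <- dataset@snpInfo$snp_id
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(body), collapse = "\t")), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genotype dosages written by [writeGenotypes()]
#'
#' @param path genotype TSV path.
#' @param snpInfo optional data.frame (\code{snp_id}, \code{chrom},
#'   \code{pos_bp}); when omitted, placeholder positions are used.
#' @return a \linkS4class{GenotypeDataset}.
#' @export
readGenotypes <- function(path, snpInfo = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  names(raw) <- cols
  snp_ids <- cols[-(1:2)]
  d <- as.matrix(raw[, -(1:2), drop = FALSE])
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  if (is.null(snpInfo))
    snpInfo <- data.frame(snp_id = snp_ids, chrom = "1",
                          pos_bp = seq_along(snp_ids),
                          stringsAsFactors = FALSE)
  new("GenotypeDataset", dosages = d,
      phenotype = factor(raw[[2]], levels = c("control", "case")),
      individualIds = as.character(raw[[1]]),
      snpInfo = snpInfo[match(snp_ids, snpInfo$snp_id), , drop = FALSE])
}

#' Write a result table as TSV with a #-prefixed header
#'
#' All pipeline result tables (gene lists, excess-of-significance tables,
#' enrichment tables) go through this writer so downstream tools see one
#' dialect.
#'
#' @param df data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResultsTsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a result table written by [writeResultsTsv()]
#'
#' @param path TSV path.
#' @return data.frame with the original column names.
#' @export
readResultsTsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           sep = "\t", stringsAsFactors = FALSE)
  names(raw) <- cols
  raw
}
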