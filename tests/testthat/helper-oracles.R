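## Exact distribution of replicate-list outcomes on a tiny SNP-gene map,
## by recursive enumeration over the SNP draw order and over the random
## truncation choice — the independent oracle for the sampling scheme.
enumerate_lists <- function(s2g, target) {
  out <- new.env(parent = emptyenv())
  add <- function(genes, snps, prob) {
    key <- paste(paste(sort(genes), collapse = ","),
                 paste(snps[order(genes)], collapse = ","), sep = ";")
    prev <- out[[key]]
    out[[key]] <- if (is.null(prev)) prob else prev + prob
  }
  recurse <- function(remaining, genes, snps, prob) {
    if (length(genes) == target) { add(genes, snps, prob); return() }
    stopifnot(length(remaining) > 0)
    p_draw <- prob / length(remaining)
    for (s in remaining) {
      fresh <- setdiff(s2g[[s]], genes)
      room <- target - length(genes)
      if (length(fresh) > room) {
        ## every size-`room` truncation equally likely; unordered subsets
        ## suffice for hit counts
        subs <- utils::combn(fresh, room, simplify = FALSE)
        for (sub in subs)
          recurse(setdiff(remaining, s), c(genes, sub),
                  c(snps, rep(s, room)), p_draw / length(subs))
      } else {
        recurse(setdiff(remaining, s), c(genes, fresh),
                c(snps, rep(s, length(fresh))), p_draw)
      }
    }
  }
  recurse(names(s2g), character(0), character(0), 1)
  as.list(out)
}

## exact P(category hits >= k) under the enumeration above
exact_tail <- function(s2g, target, set_genes, k) {
  dist <- enumerate_lists(s2g, target)
  tot <- 0
  for (key in names(dist)) {
    parts <- strsplit(key, ";", fixed = TRUE)[[1]]
    genes <- strsplit(parts[1], ",", fixed = TRUE)[[1]]
    snps <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
    hits <- length(unique(snps[genes %in% set_genes]))
    if (hits >= k) tot <- tot + dist[[key]]
  }
  tot
}
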