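#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Replicate gene lists by random SNP sampling. SNPs are drawn uniformly
// without replacement (partial Fisher-Yates over a persistent pool; the
// pool is a permutation after each replicate, which preserves uniformity);
// each drawn SNP appends its mapped genes not already on the list; when an
// append would overshoot, the offending SNP's genes are added in random
// order and truncated at exactly the target length. Uses R's RNG, so
// set.seed() governs reproducibility.
//
// snp_offsets: CSR offsets into snp_genes, length n_snps + 1 (0-based)
// snp_genes: 0-based gene indices
// Returns a list with elements "genes" and "snps": per replicate, parallel
// integer vectors of 1-based gene indices and the 1-based index of the
// sampled SNP that added each gene.
// [[Rcpp::export]]
List cpp_replicate_lists(IntegerVector snp_offsets, IntegerVector snp_genes,
                         int n_genes, int target_length, int n_replicates) {
  const int n_snps = snp_offsets.size() - 1;
  if (target_length < 0) stop("target_length must be non-negative");
  std::vector<int> pool(n_snps);
  for (int i = 0; i < n_snps; ++i) pool[i] = i;
  std::vector<int> gene_stamp(n_genes, -1);
  List out_genes(n_replicates), out_snps(n_replicates);
  std::vector<int> list_genes, list_snps, fresh;
  list_genes.reserve(target_length);
  list_snps.reserve(target_length);

  for (int r = 0; r < n_replicates; ++r) {
    list_genes.clear();
    list_snps.clear();
    int n_drawn = 0;
    while ((int)list_genes.size() < target_length && n_drawn < n_snps) {
      int j = n_drawn + (int)(unif_rand() * (n_snps - n_drawn));
      if (j >= n_snps) j = n_snps - 1;
      std::swap(pool[n_drawn], pool[j]);
      const int s = pool[n_drawn];
      ++n_drawn;
      fresh.clear();
      for (int k = snp_offsets[s]; k < snp_offsets[s + 1]; ++k) {
        const int g = snp_genes[k];
        if (gene_stamp[g] != r) fresh.push_back(g);
      }
      if (fresh.empty()) continue;
      const int room = target_length - (int)list_genes.size();
      if ((int)fresh.size() > room) {
        // random order, then truncate at the target length
        for (int a = (int)fresh.size() - 1; a > 0; --a) {
          int b = (int)(unif_rand() * (a + 1));
          if (b > a) b = a;
          std::swap(fresh[a], fresh[b]);
        }
        fresh.resize(room);
      }
      for (size_t a = 0; a < fresh.size(); ++a) {
        gene_stamp[fresh[a]] = r;
        list_genes.push_back(fresh[a] + 1);
        list_snps.push_back(s + 1);
      }
    }
    if ((int)list_genes.size() < target_length)
      stop("exhausted all SNPs before reaching the target list length");
    out_genes[r] = IntegerVector(list_genes.begin(), list_genes.end());
    out_snps[r] = IntegerVector(list_snps.begin(), list_snps.end());
  }
  return List::create(_["genes"] = out_genes, _["snps"] = out_snps);
}

// Per-replicate, per-category hit counts under the one-SNP-one-gene rule.
// On a replicate list every gene has exactly one defining SNP (the sampled
// SNP that added it), so the maximum matching size for a category equals
// the number of distinct defining SNPs among the list genes belonging to
// the category.
//
// rep_genes / rep_snps: per replicate, parallel 1-based gene indices and
//   defining-SNP indices (as produced by cpp_replicate_lists)
// gene_cat_offsets / gene_cat_ids: CSR of gene (0-based) -> category ids
//   (0-based)
// Returns an n_replicates x n_cats integer matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_hit_counts(List rep_genes, List rep_snps,
                             IntegerVector gene_cat_offsets,
                             IntegerVector gene_cat_ids,
                             int n_cats, int n_snps) {
  const int B = rep_genes.size();
  IntegerMatrix H(B, n_cats);
  std::unordered_set<long long> seen;
  const long long stride = (long long)n_snps + 1;
  for (int r = 0; r < B; ++r) {
    IntegerVector g = rep_genes[r];
    IntegerVector s = rep_snps[r];
    seen.clear();
    for (int i = 0; i < g.size(); ++i) {
      const int gi = g[i] - 1;
      const long long snp = s[i];
      for (int k = gene_cat_offsets[gi]; k < gene_cat_offsets[gi + 1]; ++k) {
        const int c = gene_cat_ids[k];
        if (seen.insert((long long)c * stride + snp).second)
          ++H(r, c);
      }
    }
  }
  return H;
}
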