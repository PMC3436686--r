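#include <Rcpp.h>
using namespace Rcpp;

// Margin-preserving randomization of a pathway-gene incidence list by
// repeated random pairwise membership swaps: pick two incidences
// (p1, g1), (p2, g2) and exchange the genes when neither (p1, g2) nor
// (p2, g1) already exists. Preserves every pathway size and every gene's
// membership count exactly. Uses R's RNG, so results are reproducible under
// set.seed().
// [[Rcpp::export]]
List swap_incidences(IntegerVector pathway, IntegerVector gene,
                     int n_pathways, int n_genes, int n_attempts) {
  const int K = pathway.size();
  IntegerVector p = clone(pathway), g = clone(gene);
  std::vector<char> memb((size_t)n_pathways * n_genes, 0);
  for (int k = 0; k < K; ++k)
    memb[(size_t)(p[k] - 1) * n_genes + (g[k] - 1)] = 1;
  int n_swapped = 0;
  for (int t = 0; t < n_attempts; ++t) {
    int i = (int)(unif_rand() * K); if (i >= K) i = K - 1;
    int j = (int)(unif_rand() * K); if (j >= K) j = K - 1;
    const int p1 = p[i] - 1, g1 = g[i] - 1, p2 = p[j] - 1, g2 = g[j] - 1;
    if (p1 == p2 || g1 == g2) continue;
    if (memb[(size_t)p1 * n_genes + g2] || memb[(size_t)p2 * n_genes + g1])
      continue;
    memb[(size_t)p1 * n_genes + g1] = 0;
    memb[(size_t)p2 * n_genes + g2] = 0;
    memb[(size_t)p1 * n_genes + g2] = 1;
    memb[(size_t)p2 * n_genes + g1] = 1;
    g[i] = g2 + 1;
    g[j] = g1 + 1;
    ++n_swapped;
  }
  return List::create(_["pathway"] = p, _["gene"] = g,
                      _["n_swapped"] = n_swapped);
}
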