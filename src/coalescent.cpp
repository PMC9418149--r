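#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Batch neutral infinite-sites coalescent. For each replicate, runs the
// standard n-coalescent (exponential waiting times with rate k(k-1)/2 while
// k lineages remain, uniformly chosen pair merges), drops mutations on each
// branch as Poisson(theta/2 * branch length), and returns the summary
// statistics the neutrality tests need: segregating sites S, mean pairwise
// differences, and the number of distinct haplotypes.
//
// Haplotype identity is tracked by giving every mutation an iid Uniform(0,1)
// increment added to the hash of each descendant tip: two tips carry the
// same mutation set iff their hashes (identical addition order) coincide.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix coal_stats(int n, double theta, int reps) {
  NumericMatrix out(reps, 3);
  RNGScope scope;
  std::vector< std::vector<int> > lin;
  std::vector<double> hash((size_t) n);
  std::vector<double> h((size_t) n);
  for (int r = 0; r < reps; ++r) {
    lin.assign((size_t) n, std::vector<int>());
    for (int i = 0; i < n; ++i) lin[(size_t) i].push_back(i);
    std::fill(hash.begin(), hash.end(), 0.0);
    int k = n;
    double S = 0.0, pisum = 0.0;
    while (k > 1) {
      double rate = k * (k - 1) / 2.0;
      double t = R::exp_rand() / rate;
      if (theta > 0) {
        for (int j = 0; j < k; ++j) {
          int m = (int) R::rpois(theta / 2.0 * t);
          for (int s = 0; s < m; ++s) {
            S += 1.0;
            double u = unif_rand();
            double c = (double) lin[(size_t) j].size();
            pisum += c * ((double) n - c);
            for (size_t q = 0; q < lin[(size_t) j].size(); ++q)
              hash[(size_t) lin[(size_t) j][q]] += u;
          }
        }
      }
      int a = (int) (unif_rand() * k);
      if (a >= k) a = k - 1;
      int b = (int) (unif_rand() * (k - 1));
      if (b >= k - 1) b = k - 2;
      if (b >= a) ++b;
      lin[(size_t) a].insert(lin[(size_t) a].end(),
                             lin[(size_t) b].begin(),
                             lin[(size_t) b].end());
      lin[(size_t) b] = lin[(size_t) (k - 1)];
      lin.pop_back();
      --k;
    }
    h = hash;
    std::sort(h.begin(), h.end());
    int kh = 1;
    for (int i = 1; i < n; ++i) if (h[(size_t) i] != h[(size_t) i - 1]) ++kh;
    out(r, 0) = S;
    out(r, 1) = pisum / (n * (n - 1) / 2.0);
    out(r, 2) = (double) kh;
  }
  return out;
}
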