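#include <Rcpp.h>
#include <string>
#include <vector>

// Maximum number of nested/juxtaposed canonical base pairs (Watson-Crick +
// G-U wobble) with a minimum hairpin loop, Nussinov-style O(n^3) dynamic
// program. N never pairs.

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// [[Rcpp::export]]
int nussinov_pairs(std::string seq, int min_loop) {
  const int n = (int)seq.size();
  if (n < min_loop + 2) return 0;
  std::vector<int> dp((size_t)n * n, 0);
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = dp[(size_t)(i + 1) * n + j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int inner = (k - i > min_loop + 1) ? dp[(size_t)(i + 1) * n + (k - 1)]
                                           : 0;
        int right = (k < j) ? dp[(size_t)(k + 1) * n + j] : 0;
        int cand = 1 + inner + right;
        if (cand > best) best = cand;
      }
      dp[(size_t)i * n + j] = best;
    }
  }
  return dp[(size_t)0 * n + (n - 1)];
}
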