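#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// canonical Watson-Crick plus G:U wobble, DNA alphabet (U stored as T)
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Maximum base-pair count secondary structure (Nussinov recursion) with
// minimum hairpin loop of 3 nt and deterministic traceback: at [i,j] prefer
// pairing i with j, then leaving i unpaired, then pairing i with the
// smallest admissible k. Returns the 1-based pair table (0 = unpaired).
// [[Rcpp::export]]
IntegerVector nussinov_pairs(std::string seq) {
  const int n = seq.size();
  IntegerVector pt(n, 0);
  if (n < 5) return pt;

  std::vector<std::vector<short>> M(n, std::vector<short>(n, 0));
  for (int len = 5; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      short best = M[i + 1][j];                     // i unpaired
      for (int k = i + 4; k <= j; ++k) {            // i paired with k
        if (!can_pair(seq[i], seq[k])) continue;
        short v = 1;
        if (i + 1 <= k - 1) v += M[i + 1][k - 1];
        if (k + 1 <= j) v += M[k + 1][j];
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }

  std::vector<std::pair<int, int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < 4 || M[i][j] == 0) continue;
    const short target = M[i][j];
    // prefer closing pair (i,j)
    if (can_pair(seq[i], seq[j])) {
      short v = 1;
      if (i + 1 <= j - 1) v += M[i + 1][j - 1];
      if (v == target) {
        pt[i] = j + 1; pt[j] = i + 1;
        stack.push_back(std::make_pair(i + 1, j - 1));
        continue;
      }
    }
    // then i unpaired
    if (M[i + 1][j] == target) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    // then i paired with the smallest admissible k < j
    bool done = false;
    for (int k = i + 4; k < j && !done; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      short v = 1;
      if (i + 1 <= k - 1) v += M[i + 1][k - 1];
      if (k + 1 <= j) v += M[k + 1][j];
      if (v == target) {
        pt[i] = k + 1; pt[k] = i + 1;
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        done = true;
      }
    }
  }
  return pt;
}
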