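#include <Rcpp.h>
#include <vector>
#include <string>

// Base-pair maximisation (Nussinov) over Watson-Crick + GU wobble pairs,
// minimum hairpin loop of 3 unpaired bases. Deterministic traceback:
// unpaired-i, then pair (i,j'), preferring larger j'.

static bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'C' && b == 'G') || (a == 'G' && b == 'C') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// [[Rcpp::export]]
Rcpp::String nussinov_fold(std::string seq, int min_loop = 3) {
  const int n = (int)seq.size();
  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i + 1][j];                       // i unpaired
      // i pairs with some k in (i, j]
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int v = 1 + (k - i >= 2 ? M[i + 1][k - 1] : 0) + (k < j ? M[k + 1][j] : 0);
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }

  std::string db(n, '.');
  // iterative traceback over interval stack
  std::vector<std::pair<int, int>> stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (M[i][j] == M[i + 1][j]) {  // i unpaired (preferred branch)
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    // find pairing partner, largest k first for determinism
    for (int k = j; k >= i + min_loop + 1; --k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int v = 1 + (k - i >= 2 ? M[i + 1][k - 1] : 0) + (k < j ? M[k + 1][j] : 0);
      if (v == M[i][j]) {
        db[i] = '(';
        db[k] = ')';
        if (k - i >= 2) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  return Rcpp::String(db);
}
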