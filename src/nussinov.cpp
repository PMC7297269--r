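#include <Rcpp.h>
#include <string>
#include <vector>

// Maximum base-pairing secondary structure (Nussinov-style DP) with
// Watson-Crick + GU wobble pairs and a minimum hairpin loop of 3 unpaired
// bases (a pair (i,j) requires j - i - 1 >= 3). Traceback is deterministic:
// at each interval the 5'-most base is paired with its 5'-most optimal
// partner when pairing attains the optimum, otherwise left unpaired.

static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'U';
  case 'U': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'U';
  case 'C': return b == 'G';
  default:  return false; // N never pairs
  }
}

// [[Rcpp::export(name = ".nussinov_cpp")]]
Rcpp::String nussinov_cpp(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  if (n == 0) return Rcpp::String("");
  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i + 1][j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int inner = (k - i - 1 > min_loop) ? M[i + 1][k - 1] : 0;
        int rest = (k < j) ? M[k + 1][j] : 0;
        int cand = 1 + inner + rest;
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }
  std::string db(n, '.');
  std::vector<std::pair<int, int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    int target = M[i][j];
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) { // 5'-most partner first
      if (!can_pair(seq[i], seq[k])) continue;
      int inner = (k - i - 1 > min_loop) ? M[i + 1][k - 1] : 0;
      int rest = (k < j) ? M[k + 1][j] : 0;
      if (1 + inner + rest == target) {
        db[i] = '(';
        db[k] = ')';
        if (k - i - 1 > min_loop) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
  return Rcpp::String(db);
}
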