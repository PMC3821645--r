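#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Pair weights: GC = 3, AT = 2, GT = 1 (pseudo-energy in favour of
// stronger pairs); 0 = not pairable. Input must be upper-case ACGT.
static inline int pair_w(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// Maximum-weight nested secondary structure with hairpin-loop constraint
// j - i > min_loop for every pair (i, j). Returns the optimal score, one
// optimal pair list (0-based, deterministic traceback preferring j unpaired,
// then the smallest pairing partner k) and the dot-bracket string.
// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop, bool traceback) {
  int n = seq.size();
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T')
      stop("non-nucleotide character in sequence");
  }
  // M[i][j], 0 <= i <= j < n, stored as vector of rows
  std::vector< std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];                      // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) { // j pairs with k
        int w = pair_w(seq[k], seq[j]);
        if (w == 0) continue;
        int left = (k > i) ? M[i][k - 1] : 0;
        int inner = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
        int cand = left + inner + w;
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }
  int score = (n > 0) ? M[0][n - 1] : 0;
  if (!traceback)
    return List::create(_["score"] = score);

  std::string db(n, '.');
  std::vector<int> pi, pj;
  std::stack< std::pair<int, int> > st;
  if (n > 1) st.push(std::make_pair(0, n - 1));
  while (!st.empty()) {
    int i = st.top().first, j = st.top().second;
    st.pop();
    if (i >= j || M[i][j] == 0) continue;
    if (M[i][j] == M[i][j - 1]) { st.push(std::make_pair(i, j - 1)); continue; }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      int w = pair_w(seq[k], seq[j]);
      if (w == 0) continue;
      int left = (k > i) ? M[i][k - 1] : 0;
      int inner = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
      if (left + inner + w == M[i][j]) {
        db[k] = '('; db[j] = ')';
        pi.push_back(k); pj.push_back(j);
        if (k > i) st.push(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) st.push(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return List::create(_["score"] = score, _["structure"] = db,
                      _["pair_i"] = wrap(pi), _["pair_j"] = wrap(pj));
}
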