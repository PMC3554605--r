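#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Optimal string alignment distance: unit-cost insertion, deletion and
// substitution plus adjacent single-character transposition.
static int osa_one(const std::string &a, const std::string &b) {
  const int n = static_cast<int>(a.size());
  const int m = static_cast<int>(b.size());
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<std::vector<int> > d(n + 1, std::vector<int>(m + 1, 0));
  for (int i = 0; i <= n; ++i) d[i][0] = i;
  for (int j = 0; j <= m; ++j) d[0][j] = j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int best = std::min(std::min(d[i - 1][j] + 1, d[i][j - 1] + 1),
                          d[i - 1][j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1]) {
        best = std::min(best, d[i - 2][j - 2] + 1);
      }
      d[i][j] = best;
    }
  }
  return d[n][m];
}

// Modified Damerau-Levenshtein: OSA operations plus transposition of two
// adjacent blocks of up to max_block characters each, at a cost equal to the
// length of the longer block.
static int mdld_one(const std::string &a, const std::string &b, int max_block) {
  const int n = static_cast<int>(a.size());
  const int m = static_cast<int>(b.size());
  if (n == 0) return m;
  if (m == 0) return n;
  if (max_block < 1) max_block = 1;
  std::vector<std::vector<int> > d(n + 1, std::vector<int>(m + 1, 0));
  for (int i = 0; i <= n; ++i) d[i][0] = i;
  for (int j = 0; j <= m; ++j) d[0][j] = j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int best = std::min(std::min(d[i - 1][j] + 1, d[i][j - 1] + 1),
                          d[i - 1][j - 1] + cost);
      // Adjacent blocks A1 (len k1) A2 (len k2) at the end of a's prefix
      // appear as A2 A1 at the end of b's prefix.
      for (int k1 = 1; k1 <= max_block; ++k1) {
        for (int k2 = 1; k2 <= max_block; ++k2) {
          const int L = k1 + k2;
          if (i < L || j < L) continue;
          bool ok = true;
          for (int x = 0; x < k1 && ok; ++x)
            if (a[i - L + x] != b[j - k1 + x]) ok = false;
          for (int x = 0; x < k2 && ok; ++x)
            if (a[i - k2 + x] != b[j - L + x]) ok = false;
          if (ok) {
            int cand = d[i - L][j - L] + std::max(k1, k2);
            if (cand < best) best = cand;
          }
        }
      }
      d[i][j] = best;
    }
  }
  return d[n][m];
}

// [[Rcpp::export]]
IntegerVector osa_distance_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = osa_one(as<std::string>(a[i]), as<std::string>(b[i]));
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector mdld_cpp(CharacterVector a, CharacterVector b, int max_block) {
  R_xlen_t n = a.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = mdld_one(as<std::string>(a[i]), as<std::string>(b[i]), max_block);
  }
  return out;
}
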