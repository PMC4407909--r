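#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with a linear gap penalty and full
// traceback. Comparison is case-insensitive; 'N'/'n' never matches.
// Spans are reported 0-based half-open on the forward orientation of the
// inputs as given. Ties in the DP are broken diagonal > up > left, and the
// first best-scoring cell in row-major order is kept, so results are
// deterministic.

static inline char upbase(char c) {
  if (c >= 'a' && c <= 'z') return c - 32;
  return c;
}

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b,
              double match = 1.0, double mismatch = -1.0, double gap = -2.0) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    stop("sw_align: empty sequence");
  // DP matrices, (n+1) x (m+1); traceback: 0 stop, 1 diag, 2 up, 3 left
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    const char ai = upbase(a[i - 1]);
    for (int j = 1; j <= m; ++j) {
      const char bj_ = upbase(b[j - 1]);
      const bool is_match = (ai == bj_) && ai != 'N';
      double d = prev[j - 1] + (is_match ? match : mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double s = d;
      unsigned char t = 1;
      if (u > s) { s = u; t = 2; }
      if (l > s) { s = l; t = 3; }
      if (s <= 0.0) { s = 0.0; t = 0; }
      cur[j] = s;
      tb[(size_t)i * (m + 1) + j] = t;
      if (s > best) { best = s; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  int i = bi, j = bj, nmatch = 0, ncol = 0;
  int qe = bi, te = bj;
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (t == 0) break;
    ++ncol;
    if (t == 1) {
      const char ai = upbase(a[i - 1]), bj_ = upbase(b[j - 1]);
      if (ai == bj_ && ai != 'N') ++nmatch;
      --i; --j;
    } else if (t == 2) {
      --i;
    } else {
      --j;
    }
  }
  return List::create(
    _["score"] = best,
    _["q_start"] = i, _["q_end"] = qe,     // 0-based half-open on query
    _["t_start"] = j, _["t_end"] = te,     // 0-based half-open on target
    _["n_match"] = nmatch, _["n_col"] = ncol);
}

// Batch version: one query against many targets; returns a numeric matrix
// with one row per target (score, q_start, q_end, t_start, t_end, n_match,
// n_col). Saves R-level call overhead in all-against-all screens.
// [[Rcpp::export(name = ".sw_align_many")]]
NumericMatrix sw_align_many(std::string a, CharacterVector targets,
                            double match = 1.0, double mismatch = -1.0,
                            double gap = -2.0) {
  const int nt = targets.size();
  NumericMatrix out(nt, 7);
  for (int k = 0; k < nt; ++k) {
    List r = sw_align(a, as<std::string>(targets[k]), match, mismatch, gap);
    out(k, 0) = as<double>(r["score"]);
    out(k, 1) = as<int>(r["q_start"]);
    out(k, 2) = as<int>(r["q_end"]);
    out(k, 3) = as<int>(r["t_start"]);
    out(k, 4) = as<int>(r["t_end"]);
    out(k, 5) = as<int>(r["n_match"]);
    out(k, 6) = as<int>(r["n_col"]);
  }
  colnames(out) = CharacterVector::create("score", "q_start", "q_end",
                                          "t_start", "t_end", "n_match", "n_col");
  return out;
}
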