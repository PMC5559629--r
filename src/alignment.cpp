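#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (end-to-end) pairwise alignment with affine gaps, Gotoh recursion.
// A gap run of length L is penalised gap_open + L * gap_extend (both passed
// as negative scores, so the first gap column already pays open + extend).
// 'N' takes the mismatch score against everything, including another 'N',
// and never counts as a matched column. Tie-breaking is deterministic:
// diagonal is preferred over a gap in the second sequence, which is
// preferred over a gap in the first.

static inline double sub_score(char a, char b, double match_s,
                               double mismatch_s) {
  if (a == 'N' || b == 'N') return mismatch_s;
  return (a == b) ? match_s : mismatch_s;
}

struct AlnResult {
  double score;
  int matches;
  int columns;
};

static AlnResult nw_one(const std::string& a, const std::string& b,
                        double match_s, double mismatch_s, double gap_open,
                        double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e300;
  const double gi = gap_open + gap_extend;  // first column of a gap run

  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);  // gap in b (consumes a)
  std::vector<double> Y((n + 1) * (m + 1), NEG);  // gap in a (consumes b)
  const int W = m + 1;
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * W] = gap_open + gap_extend * i;
  for (int j = 1; j <= m; ++j) Y[j] = gap_open + gap_extend * j;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1);
      const int u = (i - 1) * W + j, l = i * W + (j - 1);
      double s = sub_score(a[i - 1], b[j - 1], match_s, mismatch_s);
      double best = M[d];
      if (X[d] > best) best = X[d];
      if (Y[d] > best) best = Y[d];
      M[c] = best + s;
      double x = M[u] + gi;
      if (X[u] + gap_extend > x) x = X[u] + gap_extend;
      if (Y[u] + gi > x) x = Y[u] + gi;
      X[c] = x;
      double y = M[l] + gi;
      if (Y[l] + gap_extend > y) y = Y[l] + gap_extend;
      if (X[l] + gi > y) y = X[l] + gi;
      Y[c] = y;
    }
  }

  // traceback; state 0 = M, 1 = X (up), 2 = Y (left), priority M > X > Y
  int i = n, j = m;
  const int end = n * W + m;
  int state;
  double score;
  if (M[end] >= X[end] && M[end] >= Y[end]) { state = 0; score = M[end]; }
  else if (X[end] >= Y[end]) { state = 1; score = X[end]; }
  else { state = 2; score = Y[end]; }

  int matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    if (i == 0) { --j; ++columns; continue; }
    if (j == 0) { --i; ++columns; continue; }
    const int c = i * W + j, d = (i - 1) * W + (j - 1);
    const int u = (i - 1) * W + j, l = i * W + (j - 1);
    if (state == 0) {
      ++columns;
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++matches;
      if (M[d] >= X[d] && M[d] >= Y[d]) state = 0;
      else if (X[d] >= Y[d]) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      ++columns;
      double fm = M[u] + gi, fx = X[u] + gap_extend, fy = Y[u] + gi;
      if (fm >= fx && fm >= fy) state = 0;
      else if (fx >= fy) state = 1;
      else state = 2;
      --i;
    } else {
      ++columns;
      double fm = M[l] + gi, fy = Y[l] + gap_extend, fx = X[l] + gi;
      if (fm >= fy && fm >= fx) state = 0;
      else if (fy >= fx) state = 2;
      else state = 1;
      --j;
    }
  }
  AlnResult r;
  r.score = score;
  r.matches = matches;
  r.columns = columns;
  return r;
}

// [[Rcpp::export(name = ".nw_align_pairs")]]
DataFrame nw_align_pairs(CharacterVector a, CharacterVector b,
                         double match_s, double mismatch_s, double gap_open,
                         double gap_extend) {
  if (a.size() != b.size())
    stop("sequence vectors must have equal length");
  const int n = a.size();
  NumericVector score(n);
  IntegerVector matches(n), columns(n);
  for (int k = 0; k < n; ++k) {
    std::string sa = as<std::string>(a[k]);
    std::string sb = as<std::string>(b[k]);
    AlnResult r = nw_one(sa, sb, match_s, mismatch_s, gap_open, gap_extend);
    score[k] = r.score;
    matches[k] = r.matches;
    columns[k] = r.columns;
  }
  return DataFrame::create(_["score"] = score, _["matches"] = matches,
                           _["columns"] = columns);
}
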