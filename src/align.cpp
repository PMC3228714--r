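#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Semi-global Needleman-Wunsch: terminal gaps are free, internal gaps pay
// `gap` per column. Traceback is deterministic: diagonal, then up (gap in b),
// then left (gap in a). The end cell is the best-scoring cell on the last
// row/column, preferring (n,m), then the last column bottom-up, then the
// last row right-to-left.

struct AlnStats {
  std::string a, b;
  double score;
  int mismatches, internal_gap_cols, endgap_cols, compared_cols;
};

static AlnStats nw_core(const std::string& a, const std::string& b,
                        double match, double mismatch, double gap) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
  auto at = [&](int i, int j) -> double& { return H[(size_t)i * (m + 1) + j]; };
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double v = at(i - 1, j - 1) + s;
      double u = at(i - 1, j) + gap;
      double l = at(i, j - 1) + gap;
      if (u > v) v = u;
      if (l > v) v = l;
      at(i, j) = v;
    }
  }
  int ei = n, ej = m;
  double best = at(n, m);
  for (int i = n - 1; i >= 0; --i)
    if (at(i, m) > best) { best = at(i, m); ei = i; ej = m; }
  for (int j = m - 1; j >= 0; --j)
    if (at(n, j) > best) { best = at(n, j); ei = n; ej = j; }

  std::string ra, rb;  // built reversed
  for (int i = n; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  int i = ei, j = ej;
  const double eps = 1e-9;
  while (i > 0 && j > 0) {
    double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
    if (std::abs(at(i, j) - (at(i - 1, j - 1) + s)) < eps) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (std::abs(at(i, j) - (at(i - 1, j) + gap)) < eps) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
  while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  // Column classification. A terminal gap run is the maximal run of gap
  // columns at either end whose gaps all sit in the same sequence.
  const int L = (int)ra.size();
  std::vector<bool> endgap(L, false);
  if (L > 0) {
    if (ra[0] == '-' || rb[0] == '-') {
      char which = (ra[0] == '-') ? 'a' : 'b';
      for (int k = 0; k < L; ++k) {
        char g = (ra[k] == '-') ? 'a' : (rb[k] == '-' ? 'b' : 'x');
        if (g != which) break;
        endgap[k] = true;
      }
    }
    if (ra[L - 1] == '-' || rb[L - 1] == '-') {
      char which = (ra[L - 1] == '-') ? 'a' : 'b';
      for (int k = L - 1; k >= 0; --k) {
        if (endgap[k]) break;
        char g = (ra[k] == '-') ? 'a' : (rb[k] == '-' ? 'b' : 'x');
        if (g != which) break;
        endgap[k] = true;
      }
    }
  }
  AlnStats r;
  r.a = ra; r.b = rb; r.score = best;
  r.mismatches = 0; r.internal_gap_cols = 0; r.endgap_cols = 0;
  for (int k = 0; k < L; ++k) {
    bool gapcol = (ra[k] == '-' || rb[k] == '-');
    if (endgap[k]) { r.endgap_cols++; continue; }
    if (gapcol) r.internal_gap_cols++;
    else if (ra[k] != rb[k]) r.mismatches++;
  }
  r.compared_cols = L - r.endgap_cols;
  return r;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match = 1.0, double mismatch = -1.0,
                  double gap = -2.0) {
  AlnStats r = nw_core(a, b, match, mismatch, gap);
  return List::create(
    Named("aligned_a") = r.a,
    Named("aligned_b") = r.b,
    Named("score") = r.score,
    Named("mismatches") = r.mismatches,
    Named("internal_gap_cols") = r.internal_gap_cols,
    Named("endgap_cols") = r.endgap_cols,
    Named("compared_cols") = r.compared_cols);
}

// Canonical argument order for distance computation: co-optimal
// alignments can differ between (a,b) and (b,a) under the deterministic
// traceback, so distances are always computed on the ordered pair to make
// d(a,b) == d(b,a) exact.
static void canonical_order(std::string& a, std::string& b) {
  if (b.size() < a.size() || (b.size() == a.size() && b < a)) std::swap(a, b);
}

// [[Rcpp::export]]
double nw_dist_cpp(std::string a, std::string b,
                   double match = 1.0, double mismatch = -1.0,
                   double gap = -2.0) {
  canonical_order(a, b);
  AlnStats r = nw_core(a, b, match, mismatch, gap);
  if (r.compared_cols == 0) return 0.0;
  return (double)(r.mismatches + r.internal_gap_cols) / r.compared_cols;
}

// [[Rcpp::export]]
double nw_diffs_cpp(std::string a, std::string b,
                    double match = 1.0, double mismatch = -1.0,
                    double gap = -2.0) {
  canonical_order(a, b);
  AlnStats r = nw_core(a, b, match, mismatch, gap);
  return (double)(r.mismatches + r.internal_gap_cols);
}

// [[Rcpp::export]]
NumericMatrix pairwise_dist_cpp(CharacterVector seqs,
                                double match = 1.0, double mismatch = -1.0,
                                double gap = -2.0) {
  const int n = seqs.size();
  NumericMatrix d(n, n);
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      std::string x = s[i], y = s[j];
      canonical_order(x, y);
      AlnStats r = nw_core(x, y, match, mismatch, gap);
      double v = r.compared_cols == 0 ? 0.0
        : (double)(r.mismatches + r.internal_gap_cols) / r.compared_cols;
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}
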