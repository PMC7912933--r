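#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh) over a precomputed column-score
// matrix S (rows = columns of profile A, cols = columns of profile B).
// A gap of length L costs gap_open + gap_ext * L; terminal gaps are
// penalized like internal ones. Returns the optimal score and the aligned
// paths as 1-based column indices with 0 marking a gap.
//
// Tie-breaks are deterministic: diagonal > gap-in-B (consume A) >
// gap-in-A (consume B), applied both when choosing a cell's best state
// and when choosing a predecessor state.
// [[Rcpp::export(name = ".gotoh_path")]]
List gotoh_path(NumericMatrix S, double gap_open, double gap_ext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  const double open_cost = gap_open + gap_ext;

  // state 0 = M (diag), 1 = X (gap in B, consume A), 2 = Y (gap in A)
  std::vector<double> M((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> X((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> Y((size_t)(n + 1) * (m + 1), NEG);
  // predecessor state for traceback
  std::vector<signed char> pm((size_t)(n + 1) * (m + 1), -1);
  std::vector<signed char> px((size_t)(n + 1) * (m + 1), -1);
  std::vector<signed char> py((size_t)(n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(gap_open + gap_ext * i);
    px[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -(gap_open + gap_ext * j);
    py[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: from (i-1, j-1), any state; prefer M > X > Y on ties
      double a = M[at(i - 1, j - 1)], b = X[at(i - 1, j - 1)],
             c = Y[at(i - 1, j - 1)];
      double best = a;
      signed char bs = 0;
      if (b > best) { best = b; bs = 1; }
      if (c > best) { best = c; bs = 2; }
      if (best > NEG / 2) {
        M[at(i, j)] = best + S(i - 1, j - 1);
        pm[at(i, j)] = bs;
      }
      // X: consume A_i against a gap
      a = M[at(i - 1, j)] - open_cost;
      b = X[at(i - 1, j)] - gap_ext;
      c = Y[at(i - 1, j)] - open_cost;
      best = a; bs = 0;
      if (b > best) { best = b; bs = 1; }
      if (c > best) { best = c; bs = 2; }
      if (best > NEG / 2) {
        X[at(i, j)] = best;
        px[at(i, j)] = bs;
      }
      // Y: consume B_j against a gap
      a = M[at(i, j - 1)] - open_cost;
      b = X[at(i, j - 1)] - open_cost;
      c = Y[at(i, j - 1)] - gap_ext;
      best = a; bs = 0;
      if (b > best) { best = b; bs = 1; }
      if (c > best) { best = c; bs = 2; }
      if (best > NEG / 2) {
        Y[at(i, j)] = best;
        py[at(i, j)] = bs;
      }
    }
  }

  double score = M[at(n, m)];
  int state = 0;
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 2; }

  std::vector<int> pa, pb;
  pa.reserve(n + m);
  pb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    signed char prev;
    if (state == 0) {
      prev = pm[at(i, j)];
      pa.push_back(i);
      pb.push_back(j);
      --i; --j;
    } else if (state == 1) {
      prev = px[at(i, j)];
      pa.push_back(i);
      pb.push_back(0);
      --i;
    } else {
      prev = py[at(i, j)];
      pa.push_back(0);
      pb.push_back(j);
      --j;
    }
    state = prev;
  }
  const int L = (int)pa.size();
  IntegerVector ia(L), ib(L);
  for (int t = 0; t < L; ++t) {
    ia[t] = pa[L - 1 - t];
    ib[t] = pb[L - 1 - t];
  }
  return List::create(_["score"] = score, _["a"] = ia, _["b"] = ib);
}
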