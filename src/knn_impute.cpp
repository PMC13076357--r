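#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fill missing entries of `out` for the query rows `qidx` (1-based row
// indices into `out`), given the squared-distance block `d2` (one row per
// query row, one column per candidate row; Inf marks unusable candidates:
// self, or no shared observed samples). For each missing (row, col) the k
// nearest candidate rows observed in that column are averaged; the result is
// clipped to [0, 1]. Mutates `out` in place (caller owns the copy).
// [[Rcpp::export]]
void knn_fill_chunk(NumericMatrix out, NumericMatrix x, NumericMatrix d2,
                    IntegerVector qidx, int k, NumericVector row_mean) {
  const int m = x.nrow(), n = x.ncol(), q = qidx.size();
  std::vector<int> ord(m);
  for (int qi = 0; qi < q; qi++) {
    const int j = qidx[qi] - 1;
    for (int l = 0; l < m; l++) ord[l] = l;
    NumericMatrix::Row dr = d2(qi, _);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return dr[a] < dr[b]; });
    for (int i = 0; i < n; i++) {
      if (!NumericMatrix::is_na(x(j, i))) continue;
      double s = 0.0;
      int got = 0;
      for (int t = 0; t < m && got < k; t++) {
        const int l = ord[t];
        if (!R_finite(dr[l])) break;  // sorted: everything after is Inf too
        const double v = x(l, i);
        if (!NumericMatrix::is_na(v)) { s += v; got++; }
      }
      double val = got > 0 ? s / got : row_mean[j];
      if (val < 0) val = 0;
      if (val > 1) val = 1;
      out(j, i) = val;
    }
  }
}
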