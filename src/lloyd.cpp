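#include <Rcpp.h>
using namespace Rcpp;

// One Lloyd descent from an initial centroid matrix.
// Ties in the assignment step go to the lowest centroid index. Empty
// clusters are repaired by moving the point farthest from its own centroid
// (among points whose cluster keeps >= 2 members) into the empty cluster.
// [[Rcpp::export(name = ".lloyd_cpp")]]
List lloyd_cpp(NumericMatrix Z, NumericMatrix C0, int max_iter) {
  const int n = Z.nrow(), p = Z.ncol(), k = C0.nrow();
  NumericMatrix C = clone(C0);
  IntegerVector a(n, -1);
  std::vector<int> a_prev(n, -2), sizes(k);
  std::vector<double> own(n);
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      int bj = 0;
      for (int j = 0; j < k; ++j) {
        double s = 0.0;
        for (int v = 0; v < p; ++v) {
          const double d = Z(i, v) - C(j, v);
          s += d * d;
        }
        if (s < best) { best = s; bj = j; }
      }
      a[i] = bj;
      own[i] = best;
    }
    std::fill(sizes.begin(), sizes.end(), 0);
    for (int i = 0; i < n; ++i) sizes[a[i]]++;
    for (int j = 0; j < k; ++j) {
      if (sizes[j] > 0) continue;
      double best = -1.0;
      int bi = -1;
      for (int i = 0; i < n; ++i) {
        if (sizes[a[i]] <= 1) continue;
        if (own[i] > best) { best = own[i]; bi = i; }
      }
      if (bi < 0) break;
      sizes[a[bi]]--;
      a[bi] = j;
      sizes[j] = 1;
      own[bi] = 0.0;
    }
    bool same = true;
    for (int i = 0; i < n; ++i) {
      if (a[i] != a_prev[i]) { same = false; break; }
    }
    if (same) break;
    for (int i = 0; i < n; ++i) a_prev[i] = a[i];
    std::fill(C.begin(), C.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      for (int v = 0; v < p; ++v) C(a[i], v) += Z(i, v);
    }
    for (int j = 0; j < k; ++j) {
      for (int v = 0; v < p; ++v) C(j, v) /= sizes[j];
    }
  }
  double within = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int v = 0; v < p; ++v) {
      const double d = Z(i, v) - C(a[i], v);
      within += d * d;
    }
  }
  return List::create(_["assignment"] = a + 1,
                      _["centroids"] = C,
                      _["within_ss"] = within,
                      _["iterations"] = it);
}
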