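// Hot kernels for the mixed-model engine: congruence transforms of the
// precomputed cross-products with the relative-covariance factor Lambda.
//
// Lambda is represented as D + S, where D = diag(d) holds the per-column
// scale factors (sqrt variance ratios; t11/t22 for correlated
// intercept-trend blocks) and S holds the intercept-trend couplings
// S[e_k, o_k] = t21_k (column o_k of the effective design also receives
// t21 times trend column e_k).

#include <Rcpp.h>
using namespace Rcpp;

// B = (D + S)' M (D + S) + diagAdd * I, M symmetric q x q.
// [[Rcpp::export(name = ".lambdaCongruence")]]
NumericMatrix lambdaCongruence(const NumericMatrix& M, const NumericVector& d,
                               const IntegerVector& o, const IntegerVector& e,
                               const NumericVector& t, double diagAdd) {
  const int q = M.nrow(), m = o.size();
  NumericMatrix W(q, q);
  // right factor: W = M D + M S (column ops, column-major friendly)
  for (int j = 0; j < q; ++j) {
    const double dj = d[j];
    const double* mj = &M(0, j);
    double* wj = &W(0, j);
    for (int i = 0; i < q; ++i) wj[i] = mj[i] * dj;
  }
  for (int k = 0; k < m; ++k) {
    const double* me = &M(0, e[k]);
    double* wo = &W(0, o[k]);
    const double tk = t[k];
    for (int i = 0; i < q; ++i) wo[i] += tk * me[i];
  }
  // left factor: B[i, ] = d[i] W[i, ] (+ t21 W[e_k, ] when i = o_k),
  // done in place: coupled rows first (they read the still-unscaled trend
  // row), then plain scaling of all remaining rows.
  std::vector<char> done(q, 0);
  for (int k = 0; k < m; ++k) {
    const int ro = o[k], re = e[k];
    const double dro = d[ro], tk = t[k];
    for (int j = 0; j < q; ++j) W(ro, j) = dro * W(ro, j) + tk * W(re, j);
    done[ro] = 1;
  }
  for (int i = 0; i < q; ++i) {
    if (done[i]) continue;
    const double di = d[i];
    for (int j = 0; j < q; ++j) W(i, j) *= di;
  }
  for (int i = 0; i < q; ++i) W(i, i) += diagAdd;
  return W;
}

// B = (D + S)' W for a q x k right-hand side.
// [[Rcpp::export(name = ".lambdaLeft")]]
NumericMatrix lambdaLeft(const NumericMatrix& Win, const NumericVector& d,
                         const IntegerVector& o, const IntegerVector& e,
                         const NumericVector& t) {
  const int q = Win.nrow(), p = Win.ncol(), m = o.size();
  NumericMatrix B(q, p);
  for (int j = 0; j < p; ++j) {
    const double* wj = &Win(0, j);
    double* bj = &B(0, j);
    for (int i = 0; i < q; ++i) bj[i] = wj[i] * d[i];
  }
  for (int k = 0; k < m; ++k) {
    const int ro = o[k], re = e[k];
    const double tk = t[k];
    for (int j = 0; j < p; ++j) B(ro, j) += tk * Win(re, j);
  }
  return B;
}
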