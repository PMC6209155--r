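#include <Rcpp.h>
using namespace Rcpp;

// HSIC statistics for a batch of target permutations.
//
// K:  n x n feature Gram matrix.
// Lc: n x n doubly-centred target Gram matrix (H L H).  Because the
//     centring matrix H commutes with any permutation matrix P (both fix
//     the all-ones vector), permuting the target before centring equals
//     permuting Lc, so each null statistic is sum(K * Lc[p, p]) / (n-1)^2.
// P:  n x n_perm matrix of 1-based permutation indices.
//
// [[Rcpp::export(name = ".hsic_perm_stats")]]
NumericVector hsic_perm_stats(NumericMatrix K, NumericMatrix Lc,
                              IntegerMatrix P) {
  const int n = K.nrow();
  if (Lc.nrow() != n || Lc.ncol() != n || K.ncol() != n)
    stop("K and Lc must be square matrices of equal size");
  if (P.nrow() != n)
    stop("permutation matrix must have n rows");
  const int m = P.ncol();
  NumericVector out(m);
  const double denom = (double)(n - 1) * (double)(n - 1);
  for (int s = 0; s < m; ++s) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      const int pj = P(j, s) - 1;
      const double *kcol = &K(0, j);
      const double *lcol = &Lc(0, pj);
      for (int i = 0; i < n; ++i) {
        acc += kcol[i] * lcol[P(i, s) - 1];
      }
    }
    out[s] = acc / denom;
  }
  return out;
}
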