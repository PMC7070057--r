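#include <Rcpp.h>
using namespace Rcpp;

// One sequential SGD sweep over the edge list for the adjacency
// factorization objective
//   f = 1/2 * sum_{(i,j) in E} (Y_ij - <Z_i, Z_j>)^2
//       + lambda/2 * sum_i ||Z_i||^2.
// For each visited edge both endpoint rows take a descent step
//   Z_i += eta * ((Y_ij - <Z_i,Z_j>) * Z_j - lambda * Z_i)
// (and symmetrically for Z_j, using the pre-step value of Z_i), with the
// learning rate eta = 1/sqrt(t) and the global step counter t advancing
// once per edge and never resetting between sweeps. The input matrix is
// left untouched; the updated copy and the advanced counter are
// returned, with t = -1 signalling a non-finite update.
// [[Rcpp::export]]
List gf_epoch_sweep(NumericMatrix Z_in, IntegerVector ei, IntegerVector ej,
                    NumericVector y, double lambda, double t_start) {
  NumericMatrix Z = clone(Z_in);
  const int r = Z.ncol();
  const int m = ei.size();
  double t = t_start;
  for (int e = 0; e < m; ++e) {
    const int i = ei[e];
    const int j = ej[e];
    const double eta = 1.0 / std::sqrt(t);
    t += 1.0;
    double dot = 0.0;
    for (int c = 0; c < r; ++c) dot += Z(i, c) * Z(j, c);
    const double res = y[e] - dot;
    for (int c = 0; c < r; ++c) {
      const double zi = Z(i, c);
      const double zj = Z(j, c);
      const double ni = zi + eta * (res * zj - lambda * zi);
      const double nj = zj + eta * (res * zi - lambda * zj);
      if (!std::isfinite(ni) || !std::isfinite(nj)) {
        return List::create(_["Z"] = Z, _["t"] = -1.0);
      }
      Z(i, c) = ni;
      Z(j, c) = nj;
    }
  }
  return List::create(_["Z"] = Z, _["t"] = t);
}
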