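// Minimum average direct-flip (MDF) distance between equally resampled
// streamlines. Fibers are passed as an np x 3 x n cube (points in rows).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// reversal-symmetric accumulation: pair the i-th and (n-1-i)-th terms
// first so the sum is bit-identical under point-order reversal of either
// fiber (addition is commutative in IEEE floating point)
static double sym_mean(const std::vector<double>& t) {
  const size_t n = t.size();
  double s = 0.0;
  for (size_t i = 0; i < n / 2; ++i) s += t[i] + t[n - 1 - i];
  if (n % 2) s += t[n / 2];
  return s / static_cast<double>(n);
}

static double mdf_pair(const mat& A, const mat& B) {
  const uword np = A.n_rows;
  std::vector<double> td(np), tf(np);
  for (uword t = 0; t < np; ++t) {
    td[t] = norm(A.row(t) - B.row(t), 2);
    tf[t] = norm(A.row(t) - B.row(np - 1 - t), 2);
  }
  return std::min(sym_mean(td), sym_mean(tf));
}

// [[Rcpp::export]]
double cpp_mdf_distance(const arma::mat& a, const arma::mat& b) {
  if (a.n_rows != b.n_rows || a.n_cols != 3 || b.n_cols != 3)
    Rcpp::stop("fibers must share the same point count (np x 3)");
  return mdf_pair(a, b);
}

// [[Rcpp::export]]
arma::mat cpp_pairwise_mdf(const arma::cube& fibers) {
  const uword n = fibers.n_slices;
  mat D(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i)
    for (uword j = i + 1; j < n; ++j) {
      double d = mdf_pair(fibers.slice(i), fibers.slice(j));
      D(i, j) = d;
      D(j, i) = d;
    }
  return D;
}

// pairs: m x 2 matrix of 1-based fiber indices
// [[Rcpp::export]]
arma::vec cpp_mdf_pairs(const arma::cube& fibers, const arma::umat& pairs) {
  const uword m = pairs.n_rows;
  vec out(m);
  for (uword i = 0; i < m; ++i)
    out(i) = mdf_pair(fibers.slice(pairs(i, 0) - 1), fibers.slice(pairs(i, 1) - 1));
  return out;
}
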