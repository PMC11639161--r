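#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rank-1 Cholesky update/downdate of a lower-triangular factor, in place:
// L L^t  <-  L L^t + sigma * x x^t,  sigma in {+1, -1}.
// Returns TRUE on success; FALSE when a downdate loses positive definiteness,
// in which case L is left in a partially modified state and the caller must
// refactorize. Standard hyperbolic-rotation algorithm, O(p^2).
// [[Rcpp::export]]
bool chol_rank1(NumericMatrix L, NumericVector x, double sigma) {
  int p = L.nrow();
  if (L.ncol() != p || x.size() != p)
    stop("dimension mismatch in chol_rank1");
  std::vector<double> w(x.begin(), x.end());
  for (int k = 0; k < p; ++k) {
    double Lkk = L(k, k);
    double r2 = Lkk * Lkk + sigma * w[k] * w[k];
    if (r2 <= 0.0 || !std::isfinite(r2)) return false;
    double r = std::sqrt(r2);
    double c = r / Lkk;
    double s = w[k] / Lkk;
    L(k, k) = r;
    for (int i = k + 1; i < p; ++i) {
      double Lik = (L(i, k) + sigma * s * w[i]) / c;
      w[i] = c * w[i] - s * Lik;
      L(i, k) = Lik;
    }
  }
  return true;
}

// Forward substitution L u = e_j for lower-triangular L, exploiting that the
// solution is zero above index j (0-based). Used for the quadratic forms
// e_i^t (L L^t)^{-1} e_j needed by the coordinate-descent solver.
// [[Rcpp::export]]
NumericVector solve_lower_unit(NumericMatrix L, int j) {
  int p = L.nrow();
  NumericVector u(p);
  if (j < 0 || j >= p) stop("index out of range");
  u[j] = 1.0 / L(j, j);
  for (int i = j + 1; i < p; ++i) {
    double acc = 0.0;
    for (int k = j; k < i; ++k) acc += L(i, k) * u[k];
    u[i] = -acc / L(i, i);
  }
  return u;
}
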