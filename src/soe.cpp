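#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Soft ordinal embedding stress and gradient.
//
// Stress over triplets (i, j, k) = (anchor, near, far):
//   sum max(0, dist(x_j, x_i) - dist(x_i, x_k) + 1)^2
// The unit margin prevents the all-zero solution; a triplet satisfied with
// margin >= 1 contributes nothing.  These kernels are the inner loop of the
// BFGS fits, hence compiled.
//
// X: n x d coordinates; T: m x 3 triplet indices, 0-based.

static inline double pair_dist(const NumericMatrix& X, int a, int b) {
  const int d = X.ncol(), n = X.nrow();
  double s = 0.0;
  for (int c = 0; c < d; ++c) {
    const double diff = X[a + n * c] - X[b + n * c];
    s += diff * diff;
  }
  return std::sqrt(s);
}

// [[Rcpp::export]]
double soe_stress_cpp(const NumericMatrix& X, const IntegerMatrix& T) {
  const int m = T.nrow();
  double stress = 0.0;
  for (int t = 0; t < m; ++t) {
    const double h =
        pair_dist(X, T(t, 0), T(t, 1)) - pair_dist(X, T(t, 0), T(t, 2)) + 1.0;
    if (h > 0.0) stress += h * h;
  }
  return stress;
}

// Gradient of the stress.  At the hinge boundary (h == 0) the subgradient 0
// is used; a zero distance between coincident points gets a zero gradient
// direction (measure-zero event under random initialization).
// [[Rcpp::export]]
NumericMatrix soe_gradient_cpp(const NumericMatrix& X,
                               const IntegerMatrix& T) {
  const int n = X.nrow(), d = X.ncol(), m = T.nrow();
  NumericMatrix G(n, d);
  for (int t = 0; t < m; ++t) {
    const int i = T(t, 0), j = T(t, 1), k = T(t, 2);
    const double dn = pair_dist(X, i, j);
    const double df = pair_dist(X, i, k);
    const double h = dn - df + 1.0;
    if (h <= 0.0) continue;
    const double w = 2.0 * h;
    for (int c = 0; c < d; ++c) {
      const double xi = X[i + n * c];
      // d dn / dx: (x_j - x_i)/dn for j, opposite for i; zero if dn == 0
      if (dn > 0.0) {
        const double g = w * (X[j + n * c] - xi) / dn;
        G[j + n * c] += g;
        G[i + n * c] -= g;
      }
      // -d df / dx enters with opposite sign
      if (df > 0.0) {
        const double g = w * (X[k + n * c] - xi) / df;
        G[k + n * c] -= g;
        G[i + n * c] += g;
      }
    }
  }
  return G;
}
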