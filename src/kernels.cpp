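// Hot numerical kernels: 3x3 same-padding convolution (decoder refinement
// blocks) and the pairwise additive attention logits of the GAT layer.
// Both have matching analytic backward passes; the R test suite verifies
// them against numerical gradients.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double lrelu(double x, double slope) {
  return x > 0 ? x : slope * x;
}
static inline double lrelu_grad(double x, double slope) {
  return x > 0 ? 1.0 : slope;
}

// X: n x n x cin, Kmat: (9*cin) x cout with row index dy + 3*dx + 9*ci
// (0-based offsets dy, dx in {0,1,2} meaning shifts -1..1), b: cout.
// [[Rcpp::export]]
arma::cube conv3x3_fwd(const arma::cube& X, const arma::mat& Kmat,
                       const arma::vec& b) {
  const int n = X.n_rows;
  const int cin = X.n_slices;
  const int cout = Kmat.n_cols;
  arma::cube Y(n, n, cout);
  for (int co = 0; co < cout; ++co) Y.slice(co).fill(b[co]);
  for (int co = 0; co < cout; ++co) {
    arma::mat& Yc = Y.slice(co);
    for (int ci = 0; ci < cin; ++ci) {
      const arma::mat& Xc = X.slice(ci);
      for (int dx = 0; dx < 3; ++dx) {
        for (int dy = 0; dy < 3; ++dy) {
          const double k = Kmat(dy + 3 * dx + 9 * ci, co);
          if (k == 0.0) continue;
          const int r0 = std::max(0, 1 - dy), r1 = std::min(n, n + 1 - dy);
          const int c0 = std::max(0, 1 - dx), c1 = std::min(n, n + 1 - dx);
          for (int c = c0; c < c1; ++c) {
            const double* xcol = Xc.colptr(c + dx - 1);
            double* ycol = Yc.colptr(c);
            for (int r = r0; r < r1; ++r) {
              ycol[r] += k * xcol[r + dy - 1];
            }
          }
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List conv3x3_bwd(const arma::cube& dY, const arma::cube& X,
                 const arma::mat& Kmat) {
  const int n = X.n_rows;
  const int cin = X.n_slices;
  const int cout = Kmat.n_cols;
  arma::cube dX(n, n, cin, arma::fill::zeros);
  arma::mat dK(9 * cin, cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  for (int co = 0; co < cout; ++co) {
    const arma::mat& dYc = dY.slice(co);
    db[co] = arma::accu(dYc);
    for (int ci = 0; ci < cin; ++ci) {
      const arma::mat& Xc = X.slice(ci);
      arma::mat& dXc = dX.slice(ci);
      for (int dx = 0; dx < 3; ++dx) {
        for (int dy = 0; dy < 3; ++dy) {
          const double k = Kmat(dy + 3 * dx + 9 * ci, co);
          double gk = 0.0;
          const int r0 = std::max(0, 1 - dy), r1 = std::min(n, n + 1 - dy);
          const int c0 = std::max(0, 1 - dx), c1 = std::min(n, n + 1 - dx);
          for (int c = c0; c < c1; ++c) {
            const double* xcol = Xc.colptr(c + dx - 1);
            double* dxcol = dXc.colptr(c + dx - 1);
            const double* dycol = dYc.colptr(c);
            for (int r = r0; r < r1; ++r) {
              gk += xcol[r + dy - 1] * dycol[r];
              dxcol[r + dy - 1] += k * dycol[r];
            }
          }
          dK(dy + 3 * dx + 9 * ci, co) += gk;
        }
      }
    }
  }
  return List::create(Named("dX") = dX, Named("dK") = dK,
                      Named("db") = db);
}

// logits(i, j) = sum_k a_k * LeakyReLU(S1(i,k) + S2(j,k) + w3_k * E(i,j))
// [[Rcpp::export]]
arma::mat gat_logits_fwd(const arma::mat& S1, const arma::mat& S2,
                         const arma::mat& E, const arma::vec& w3,
                         const arma::vec& a, double slope) {
  const int n = S1.n_rows;
  const int d = S1.n_cols;
  arma::mat logits(n, n, arma::fill::zeros);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      const double e = E(i, j);
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        s += a[k] * lrelu(S1(i, k) + S2(j, k) + w3[k] * e, slope);
      }
      logits(i, j) = s;
    }
  }
  return logits;
}

// dl: n x n upstream gradient on the logits (already masked).
// [[Rcpp::export]]
List gat_logits_bwd(const arma::mat& dl, const arma::mat& S1,
                    const arma::mat& S2, const arma::mat& E,
                    const arma::vec& w3, const arma::vec& a, double slope) {
  const int n = S1.n_rows;
  const int d = S1.n_cols;
  arma::mat dS1(n, d, arma::fill::zeros);
  arma::mat dS2(n, d, arma::fill::zeros);
  arma::vec dw3(d, arma::fill::zeros);
  arma::vec da(d, arma::fill::zeros);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      const double g = dl(i, j);
      if (g == 0.0) continue;
      const double e = E(i, j);
      for (int k = 0; k < d; ++k) {
        const double u = S1(i, k) + S2(j, k) + w3[k] * e;
        da[k] += g * lrelu(u, slope);
        const double gu = g * a[k] * lrelu_grad(u, slope);
        dS1(i, k) += gu;
        dS2(j, k) += gu;
        dw3[k] += gu * e;
      }
    }
  }
  return List::create(Named("dS1") = dS1, Named("dS2") = dS2,
                      Named("dw3") = dw3, Named("da") = da);
}
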