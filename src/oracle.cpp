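#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Transfer-matrix evaluation of the fixed-centroid ring-polymer trace.
//
// The centroid-constrained bead density at centroid c is
//   rho_c(c) = (P / 2 pi) Int dlambda e^{-i lambda P c} Tr[ B(lambda)^P ]
// with B(lambda)_{ab} = dx * exp(-m P (x_a - x_b)^2 / (2 beta hbar^2))
//                      * exp(-beta (U_a + U_b) / (2P))
//                      * exp(i lambda (x_a + x_b) / 2),
// i.e. the delta constraint on the bead mean is Fourier-resolved and
// each bead carries a phase e^{i lambda x_k}.  Up to a lambda-
// independent constant (which cancels in forces and normalised
// densities) this returns G(lambda) = Tr[B(lambda)^P] for each lambda,
// computed by repeated squaring (P must be a power of two).  A common
// real rescaling keeps magnitudes representable for large P.
//
// m is in kJ/mol fs^2/A^2; U in kJ/mol on the x grid (Angstrom).
// [[Rcpp::export]]
ComplexVector oracle_trace(NumericVector xgrid, NumericVector Ugrid,
                           double m, double TK, int P,
                           NumericVector lambdas) {
  const double KB = 0.00831446261815324;
  const double HBAR = 63.507799235029601;
  const double beta = 1.0 / (KB * TK);
  const int nx = xgrid.size();
  if ((P & (P - 1)) != 0 || P < 2) stop("P must be a power of two >= 2");
  const double dx = xgrid[1] - xgrid[0];
  const double spring = m * P / (2.0 * beta * HBAR * HBAR);

  arma::vec x(xgrid.begin(), nx), U(Ugrid.begin(), nx);
  arma::mat R(nx, nx);
  for (int a = 0; a < nx; ++a)
    for (int b = 0; b < nx; ++b) {
      double d = x[a] - x[b];
      R(a, b) = dx * std::exp(-spring * d * d - beta * (U[a] + U[b]) / (2.0 * P));
    }
  // lambda-independent rescale so powers stay representable
  double s0 = arma::max(arma::sum(R, 1));
  R /= s0;

  int n_sq = 0;
  for (int t = P; t > 1; t >>= 1) ++n_sq;

  ComplexVector out(lambdas.size());
  for (int il = 0; il < lambdas.size(); ++il) {
    double lam = lambdas[il];
    arma::cx_mat B(nx, nx);
    for (int a = 0; a < nx; ++a)
      for (int b = 0; b < nx; ++b) {
        double ph = 0.5 * lam * (x[a] + x[b]);
        B(a, b) = R(a, b) * std::complex<double>(std::cos(ph), std::sin(ph));
      }
    for (int s = 0; s < n_sq; ++s) B = B * B;
    std::complex<double> tr = arma::trace(B);
    out[il] = Rcomplex{tr.real(), tr.imag()};
  }
  return out;
}
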