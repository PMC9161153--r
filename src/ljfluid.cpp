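#include <Rcpp.h>
using namespace Rcpp;

// Minimum-image shifted-force Lennard-Jones energy/forces/virial for a
// monoatomic periodic fluid.  Positions are N x 3 (Angstrom),
// orthorhombic cell.  The pair virial returned is sum_{i<j} r_ij . f_ij.
// [[Rcpp::export]]
List lj_fluid_eval(NumericMatrix pos, NumericVector cell, double eps,
                   double sigma, double rcut) {
  const int n = pos.nrow();
  NumericMatrix forces(n, 3);
  double energy = 0.0, virial = 0.0;
  const double rc2 = rcut * rcut;
  // shift terms at the cutoff
  const double sr6c = std::pow(sigma / rcut, 6);
  const double u_rc = 4.0 * eps * (sr6c * sr6c - sr6c);
  const double du_rc = (-48.0 * eps * sr6c * sr6c + 24.0 * eps * sr6c) / rcut;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d[3];
      double r2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double dk = pos(i, k) - pos(j, k);
        dk -= cell[k] * std::round(dk / cell[k]);
        d[k] = dk;
        r2 += dk * dk;
      }
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      double sr6 = std::pow(sigma / r, 6);
      double u = 4.0 * eps * (sr6 * sr6 - sr6);
      double du = (-48.0 * eps * sr6 * sr6 + 24.0 * eps * sr6) / r;
      energy += u - u_rc - du_rc * (r - rcut);
      double fmag_over_r = -(du - du_rc) / r;  // force on i along d
      for (int k = 0; k < 3; ++k) {
        double f = fmag_over_r * d[k];
        forces(i, k) += f;
        forces(j, k) -= f;
      }
      virial += fmag_over_r * r2;  // r_ij . f_ij
    }
  }
  return List::create(_["energy"] = energy, _["forces"] = forces,
                      _["virial"] = virial);
}
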