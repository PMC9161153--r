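#include <Rcpp.h>
#include <vector>
#include "mlcmd_rng.h"
using namespace Rcpp;

// kB in kJ/(mol K), hbar in kJ fs/mol; masses below are in
// kJ/mol fs^2/Angstrom^2 so no further conversion appears.
static const double KB = 0.00831446261815324;
static const double HBAR = 63.507799235029601;

static inline double u1d_cpp(int kind, const double *par, double x) {
  switch (kind) {
    case 0: return 0.0;
    case 1: return 0.5 * par[0] * x * x;
    case 2: return 0.25 * par[0] * x * x * x * x;
    case 3: { double e = std::exp(-par[1] * x); double q = 1.0 - e;
              return par[0] * q * q; }
  }
  return 0.0;
}

static inline double du1d_cpp(int kind, const double *par, double x) {
  switch (kind) {
    case 0: return 0.0;
    case 1: return par[0] * x;
    case 2: return par[0] * x * x * x;
    case 3: { double e = std::exp(-par[1] * x);
              return 2.0 * par[0] * par[1] * e * (1.0 - e); }
  }
  return 0.0;
}

// One-dimensional ring-polymer sampler: normal-mode representation,
// exact free-ring-polymer evolution, per-mode Langevin (PILE) friction
// in a BAOAB splitting.  The ring polymer is sampled at the physical
// temperature with spring frequency omega_P = sqrt(P)/(beta hbar) and
// the physical potential entering as U/P per bead, so the mean of the
// full physical force over beads estimates the quantum centroid force.
//
// kind: 0 free, 1 harmonic (par = k), 2 quartic (par = c),
//       3 morse (par = D, a).  m is in kJ/mol fs^2/A^2.
// gamma: centroid-mode friction in 1/fs (0 = no thermostat anywhere).
// If fixed_centroid, the centroid mode is frozen at x_c (momentum
// zeroed), which realises the delta-constrained bead average.
// [[Rcpp::export]]
List rp1d_sample(int kind, NumericVector par, double m, double TK, int P,
                 int n_steps, double dt, double gamma, double x_c,
                 bool fixed_centroid, int seed, double burn_frac,
                 int n_blocks, int collect_stride, bool collapsed_start) {
  if (P < 1) stop("P must be >= 1");
  const double beta = 1.0 / (KB * TK);
  const double omegaP = std::sqrt((double)P) / (beta * HBAR);
  const double kT = KB * TK;
  std::vector<double> pvec(par.begin(), par.end());
  const double *pp = pvec.data();

  // orthonormal normal-mode matrix C (x = C q), mode frequencies
  std::vector<double> C(P * P), wk(P);
  for (int k = 0; k < P; ++k) {
    wk[k] = 2.0 * omegaP * std::sin(M_PI * k / P);
    for (int j = 0; j < P; ++j) {
      double val;
      if (k == 0) val = std::sqrt(1.0 / P);
      else if (2 * k == P) val = std::sqrt(1.0 / P) * ((j % 2) ? -1.0 : 1.0);
      else if (2 * k < P) val = std::sqrt(2.0 / P) * std::cos(2.0 * M_PI * j * k / P);
      else val = std::sqrt(2.0 / P) * std::sin(2.0 * M_PI * j * (P - k) / P);
      C[j * P + k] = val;
    }
  }

  MlcmdRng rng((uint64_t)seed);
  std::vector<double> q(P, 0.0), p(P, 0.0), x(P), fq(P), fx(P);
  q[0] = std::sqrt((double)P) * x_c;
  if (!collapsed_start) {
    // thermalised free-ring-polymer start for the internal modes
    for (int k = 1; k < P; ++k)
      q[k] = std::sqrt(kT / (m * wk[k] * wk[k])) * rng.gauss();
  }
  double sd_p = std::sqrt(m * kT);
  for (int k = 0; k < P; ++k) p[k] = sd_p * rng.gauss();
  if (fixed_centroid) p[0] = 0.0;

  // Langevin coefficients (PILE: internal friction 2 w_k)
  std::vector<double> c1(P), c2(P);
  for (int k = 0; k < P; ++k) {
    double g = (k == 0) ? gamma : 2.0 * wk[k];
    c1[k] = std::exp(-g * dt);
    c2[k] = std::sqrt(m * kT * (1.0 - c1[k] * c1[k]));
  }
  const bool thermostat = gamma > 0.0;
  std::vector<double> cwt(P), swt(P);
  for (int k = 0; k < P; ++k) {
    cwt[k] = std::cos(wk[k] * 0.5 * dt);
    swt[k] = std::sin(wk[k] * 0.5 * dt);
  }

  // bead positions and physical mode forces at current q
  auto to_beads = [&](void) {
    for (int j = 0; j < P; ++j) {
      double s = 0.0;
      for (int k = 0; k < P; ++k) s += C[j * P + k] * q[k];
      x[j] = s;
    }
  };
  auto mode_forces = [&](void) {
    for (int j = 0; j < P; ++j) fx[j] = -du1d_cpp(kind, pp, x[j]) / P;
    for (int k = 0; k < P; ++k) {
      double s = 0.0;
      for (int j = 0; j < P; ++j) s += C[j * P + k] * fx[j];
      fq[k] = s;
    }
  };

  to_beads();
  mode_forces();

  const int n_burn = (int)std::floor(burn_frac * n_steps);
  const int n_meas = n_steps - n_burn;
  if (n_meas < n_blocks) stop("too few measurement steps for block averaging");
  const int block_len = n_meas / n_blocks;
  std::vector<double> block_force(n_blocks, 0.0);
  double sum_force = 0.0, sum_width = 0.0, sum_virial = 0.0;
  std::vector<double> block_width(n_blocks, 0.0);
  std::vector<double> e_samp, xc_samp;

  for (int step = 0; step < n_steps; ++step) {
    // B: half kick
    for (int k = 0; k < P; ++k) p[k] += 0.5 * dt * fq[k];
    if (fixed_centroid) p[0] = 0.0;
    // A: half exact free-RP evolution
    for (int k = 0; k < P; ++k) {
      if (k == 0) {
        if (!fixed_centroid) q[0] += 0.5 * dt * p[0] / m;
      } else {
        double w = wk[k];
        double qn = q[k] * cwt[k] + p[k] / (m * w) * swt[k];
        p[k] = p[k] * cwt[k] - m * w * q[k] * swt[k];
        q[k] = qn;
      }
    }
    // O: per-mode OU
    if (thermostat) {
      for (int k = 0; k < P; ++k) {
        if (k == 0 && fixed_centroid) { p[0] = 0.0; continue; }
        if (k == 0 || wk[k] > 0.0)
          p[k] = c1[k] * p[k] + c2[k] * rng.gauss();
      }
    }
    // A: second half
    for (int k = 0; k < P; ++k) {
      if (k == 0) {
        if (!fixed_centroid) q[0] += 0.5 * dt * p[0] / m;
      } else {
        double w = wk[k];
        double qn = q[k] * cwt[k] + p[k] / (m * w) * swt[k];
        p[k] = p[k] * cwt[k] - m * w * q[k] * swt[k];
        q[k] = qn;
      }
    }
    // B: half kick at new positions
    to_beads();
    mode_forces();
    for (int k = 0; k < P; ++k) p[k] += 0.5 * dt * fq[k];
    if (fixed_centroid) p[0] = 0.0;

    if (step >= n_burn) {
      int im = step - n_burn;
      double fbar = 0.0;
      for (int j = 0; j < P; ++j) fbar -= du1d_cpp(kind, pp, x[j]);
      fbar /= P;
      double xc_now = q[0] / std::sqrt((double)P);
      double w2 = 0.0, vir = 0.0;
      for (int j = 0; j < P; ++j) {
        double dxj = x[j] - xc_now;
        w2 += dxj * dxj;
        vir += dxj * (-du1d_cpp(kind, pp, x[j]));  // (x_k - x_c) . F(x_k)
      }
      w2 /= P;
      vir /= P;
      sum_virial += vir;
      sum_force += fbar;
      sum_width += w2;
      int ib = im / block_len;
      if (ib < n_blocks) {  // drop the ragged remainder from the blocks
        block_force[ib] += fbar;
        block_width[ib] += w2;
      }
      if (collect_stride > 0 && im % collect_stride == 0) {
        double e = 0.0;
        for (int k = 0; k < P; ++k)
          e += p[k] * p[k] / (2.0 * m) + 0.5 * m * wk[k] * wk[k] * q[k] * q[k];
        for (int j = 0; j < P; ++j) e += u1d_cpp(kind, pp, x[j]) / P;
        e_samp.push_back(e);
        xc_samp.push_back(xc_now);
      }
    }
  }

  double mean_force = sum_force / n_meas;
  double mean_width = sum_width / n_meas;
  double varf = 0.0, varw = 0.0;
  for (int b = 0; b < n_blocks; ++b) {
    double bf = block_force[b] / block_len - mean_force;
    double bw = block_width[b] / block_len - mean_width;
    varf += bf * bf;
    varw += bw * bw;
  }
  double sem_force = std::sqrt(varf / (n_blocks - 1.0) / n_blocks);
  double sem_width = std::sqrt(varw / (n_blocks - 1.0) / n_blocks);

  return List::create(
    _["mean_force"] = mean_force, _["force_sem"] = sem_force,
    _["width"] = mean_width, _["width_sem"] = sem_width,
    _["mean_virial"] = sum_virial / n_meas,
    _["n_meas"] = n_meas,
    _["energies"] = NumericVector(e_samp.begin(), e_samp.end()),
    _["xc"] = NumericVector(xc_samp.begin(), xc_samp.end()));
}
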