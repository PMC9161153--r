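#include <Rcpp.h>
#include <vector>
#include "mlcmd_rng.h"
using namespace Rcpp;

static const double KB1 = 0.00831446261815324;

static inline double du1d_md(int kind, const double *par, double x) {
  switch (kind) {
    case 0: return 0.0;
    case 1: return par[0] * x;
    case 2: return par[0] * x * x * x;
    case 3: { double e = std::exp(-par[1] * x);
              return 2.0 * par[0] * par[1] * e * (1.0 - e); }
  }
  return 0.0;
}

// Correction force from a coordinate-basis network: features are
// Gaussians phi_i(x) = exp(-(x-c_i)^2 / (2 w^2)), scalar u = w3.tanh(
// W2 tanh(W1 phi + b1) + b2), force = -du/dx.
struct Net1d {
  int nf, n1, n2;
  std::vector<double> centers;
  double width;
  std::vector<double> W1, b1, W2, b2, w3;  // row-major W1[n1][nf], W2[n2][n1]

  double force(double x) const {
    std::vector<double> phi(nf), dphi(nf);
    for (int i = 0; i < nf; ++i) {
      double d = (x - centers[i]) / width;
      phi[i] = std::exp(-0.5 * d * d);
      dphi[i] = -d / width * phi[i];
    }
    std::vector<double> a1(n1), d1(n1), a2(n2), d2(n2);
    for (int i = 0; i < n1; ++i) {
      double z = b1[i];
      for (int j = 0; j < nf; ++j) z += W1[i * nf + j] * phi[j];
      a1[i] = std::tanh(z);
      d1[i] = 1.0 - a1[i] * a1[i];
    }
    for (int i = 0; i < n2; ++i) {
      double z = b2[i];
      for (int j = 0; j < n1; ++j) z += W2[i * n1 + j] * a1[j];
      a2[i] = std::tanh(z);
      d2[i] = 1.0 - a2[i] * a2[i];
    }
    // g = W1' (d1 o (W2' (d2 o w3)))
    std::vector<double> v2(n2), v1(n1, 0.0);
    for (int i = 0; i < n2; ++i) v2[i] = d2[i] * w3[i];
    for (int j = 0; j < n1; ++j) {
      double s = 0.0;
      for (int i = 0; i < n2; ++i) s += W2[i * n1 + j] * v2[i];
      v1[j] = d1[j] * s;
    }
    double du = 0.0;  // du/dx = sum_j g_j dphi_j/dx
    for (int j = 0; j < nf; ++j) {
      double gj = 0.0;
      for (int i = 0; i < n1; ++i) gj += W1[i * nf + j] * v1[i];
      du += gj * dphi[j];
    }
    return -du;
  }
};

// Classical or correction-augmented 1D Langevin dynamics (BAOAB).
// Returns positions sampled every `stride` steps after burn-in.
// [[Rcpp::export]]
NumericVector md1d_run(int kind, NumericVector par, double m, double TK,
                       double dt, double gamma, int n_steps, int stride,
                       double burn_frac, int seed, double x0,
                       bool has_corr, List corr) {
  std::vector<double> pvec(par.begin(), par.end());
  const double *pp = pvec.data();
  Net1d net;
  if (has_corr) {
    NumericVector ctr = corr["centers"];
    net.centers.assign(ctr.begin(), ctr.end());
    net.width = as<double>(corr["width"]);
    NumericMatrix W1 = corr["W1"], W2 = corr["W2"];
    NumericVector b1 = corr["b1"], b2 = corr["b2"], w3 = corr["w3"];
    net.nf = W1.ncol(); net.n1 = W1.nrow(); net.n2 = W2.nrow();
    net.W1.resize(net.n1 * net.nf);
    for (int i = 0; i < net.n1; ++i)
      for (int j = 0; j < net.nf; ++j) net.W1[i * net.nf + j] = W1(i, j);
    net.W2.resize(net.n2 * net.n1);
    for (int i = 0; i < net.n2; ++i)
      for (int j = 0; j < net.n1; ++j) net.W2[i * net.n1 + j] = W2(i, j);
    net.b1.assign(b1.begin(), b1.end());
    net.b2.assign(b2.begin(), b2.end());
    net.w3.assign(w3.begin(), w3.end());
  }

  MlcmdRng rng((uint64_t)seed);
  const double kT = KB1 * TK;
  double x = x0, p = std::sqrt(m * kT) * rng.gauss();
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(m * kT * (1.0 - c1 * c1));
  auto force = [&](double xx) {
    double f = -du1d_md(kind, pp, xx);
    if (has_corr) f += net.force(xx);
    return f;
  };
  double f = force(x);
  int n_burn = (int)std::floor(burn_frac * n_steps);
  std::vector<double> samples;
  samples.reserve((n_steps - n_burn) / stride + 1);
  for (int step = 0; step < n_steps; ++step) {
    p += 0.5 * dt * f;
    x += 0.5 * dt * p / m;
    if (gamma > 0.0) p = c1 * p + c2 * rng.gauss();
    x += 0.5 * dt * p / m;
    f = force(x);
    p += 0.5 * dt * f;
    if (step >= n_burn && (step - n_burn) % stride == 0)
      samples.push_back(x);
  }
  return NumericVector(samples.begin(), samples.end());
}
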