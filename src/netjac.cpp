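#include <Rcpp.h>
using namespace Rcpp;

// Analytic Jacobian d g / d theta of the network feature-gradient
// g = W1' (d1 o (W2' (d2 o w3))) with respect to all weights, in the
// packing order c(vec(W1), b1, vec(W2), b2, w3).  Mirrors the R
// reference implementation (kept for testing); hot path of the
// Levenberg-Marquardt force-matching stage.
// [[Rcpp::export]]
NumericMatrix net_g_jac_cpp(NumericMatrix W1, NumericVector b1,
                            NumericMatrix W2, NumericVector b2,
                            NumericVector w3, NumericVector f) {
  const int n1 = W1.nrow(), nf = W1.ncol(), n2 = W2.nrow();
  std::vector<double> z1(n1), a1(n1), d1(n1), dd1(n1);
  for (int i = 0; i < n1; ++i) {
    double z = b1[i];
    for (int j = 0; j < nf; ++j) z += W1(i, j) * f[j];
    a1[i] = std::tanh(z);
    d1[i] = 1.0 - a1[i] * a1[i];
    dd1[i] = -2.0 * a1[i] * d1[i];
  }
  std::vector<double> a2(n2), d2(n2), dd2(n2), v2(n2);
  for (int i = 0; i < n2; ++i) {
    double z = b2[i];
    for (int j = 0; j < n1; ++j) z += W2(i, j) * a1[j];
    a2[i] = std::tanh(z);
    d2[i] = 1.0 - a2[i] * a2[i];
    dd2[i] = -2.0 * a2[i] * d2[i];
    v2[i] = d2[i] * w3[i];
  }
  std::vector<double> w2tv2(n1), v1(n1);
  for (int j = 0; j < n1; ++j) {
    double s = 0.0;
    for (int i = 0; i < n2; ++i) s += W2(i, j) * v2[i];
    w2tv2[j] = s;
    v1[j] = d1[j] * s;
  }
  // M1 = W1' diag(d1): nf x n1
  std::vector<double> M1(nf * n1);
  for (int j = 0; j < n1; ++j)
    for (int q = 0; q < nf; ++q)
      M1[q + j * nf] = W1(j, q) * d1[j];
  // dg_dw3[q, k] = sum_j M1[q, j] W2(k, j) d2[k]
  // dg_db2[q, k] = sum_j M1[q, j] W2(k, j) dd2[k] w3[k]
  std::vector<double> dg_dw3(nf * n2), dg_db2(nf * n2);
  for (int k = 0; k < n2; ++k)
    for (int q = 0; q < nf; ++q) {
      double s = 0.0;
      for (int j = 0; j < n1; ++j) s += M1[q + j * nf] * W2(k, j);
      dg_dw3[q + k * nf] = s * d2[k];
      dg_db2[q + k * nf] = s * dd2[k] * w3[k];
    }
  // S = W2' diag(dd2 o w3) W2 (n1 x n1)
  std::vector<double> S(n1 * n1);
  for (int j = 0; j < n1; ++j)
    for (int l = 0; l < n1; ++l) {
      double s = 0.0;
      for (int i = 0; i < n2; ++i) s += W2(i, j) * dd2[i] * w3[i] * W2(i, l);
      S[j + l * n1] = s;
    }
  // dg_db1[q, k] = W1t[q, k] dd1[k] w2tv2[k]
  //              + sum_j W1t[q, j] d1[j] S[j, k] d1[k]
  std::vector<double> dg_db1(nf * n1);
  for (int k = 0; k < n1; ++k)
    for (int q = 0; q < nf; ++q) {
      double s = W1(k, q) * dd1[k] * w2tv2[k];
      for (int j = 0; j < n1; ++j)
        s += W1(j, q) * d1[j] * S[j + k * n1] * d1[k];
      dg_db1[q + k * nf] = s;
    }

  const int npar = n1 * nf + n1 + n2 * n1 + n2 + n2;
  NumericMatrix J(nf, npar);
  int off = 0;
  // W1 blocks: column (j, k) at (j * n1 + k): delta_{qj} v1[k] + f[j] dg_db1[, k]
  for (int j = 0; j < nf; ++j)
    for (int k = 0; k < n1; ++k) {
      double* col = &J(0, off + j * n1 + k);
      for (int q = 0; q < nf; ++q) col[q] = f[j] * dg_db1[q + k * nf];
      col[j] += v1[k];
    }
  off += n1 * nf;
  for (int k = 0; k < n1; ++k) {
    double* col = &J(0, off + k);
    for (int q = 0; q < nf; ++q) col[q] = dg_db1[q + k * nf];
  }
  off += n1;
  // W2 blocks: column (j, k) at (j * n2 + k): v2[k] M1[, j] + a1[j] dg_db2[, k]
  for (int j = 0; j < n1; ++j)
    for (int k = 0; k < n2; ++k) {
      double* col = &J(0, off + j * n2 + k);
      for (int q = 0; q < nf; ++q)
        col[q] = v2[k] * M1[q + j * nf] + a1[j] * dg_db2[q + k * nf];
    }
  off += n2 * n1;
  for (int k = 0; k < n2; ++k) {
    double* col = &J(0, off + k);
    for (int q = 0; q < nf; ++q) col[q] = dg_db2[q + k * nf];
  }
  off += n2;
  for (int k = 0; k < n2; ++k) {
    double* col = &J(0, off + k);
    for (int q = 0; q < nf; ++q) col[q] = dg_dw3[q + k * nf];
  }
  return J;
}
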