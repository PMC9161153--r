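# Pair-vectorized evaluation of correction forces for environment-mode
# models: used by predict() so ML-CMD runs at classical-force cost.
# Builds the neighbour pair list once, accumulates the embedded
# densities S and their gradients per pair, and contracts with the
# batched network gradients -- no per-atom Jacobian blocks.

.net_g_batch <- function(net, Fmat) {
  Z1 <- tcrossprod(Fmat, net$W1)
  Z1 <- sweep(Z1, 2, net$b1, "+")
  A1 <- tanh(Z1); D1 <- 1 - A1^2
  Z2 <- tcrossprod(A1, net$W2)
  Z2 <- sweep(Z2, 2, net$b2, "+")
  A2 <- tanh(Z2); D2 <- 1 - A2^2
  V2 <- sweep(D2, 2, net$w3, "*")
  V1 <- D1 * (V2 %*% net$W2)
  list(G = V1 %*% net$W1, u = as.vector(A2 %*% net$w3))
}

.rowsum_pad <- function(x, group, n) {
  # dense rowsum over groups 1..n (x a matrix or vector)
  x <- as.matrix(x)
  rowsum(rbind(x, matrix(0, n, ncol(x))), c(group, seq_len(n)))
}

.predict_env_forces <- function(object, config) {
  params <- object$params
  n <- n_atoms(config)
  pos <- config$positions
  rc <- params$cutoff
  if (config$periodic && rc > min(config$cell) / 2 + 1e-12)
    stop("descriptor cutoff exceeds half the shortest box edge")
  miss <- setdiff(unique(config$elements), object$elements)
  if (length(miss))
    stop("model not trained for element(s): ", paste(miss, collapse = ", "))
  # ordered neighbour pairs (a = owner, b = neighbour)
  ii <- rep(seq_len(n), each = n); jj <- rep(seq_len(n), times = n)
  keep <- ii != jj
  d <- pos[jj[keep], , drop = FALSE] - pos[ii[keep], , drop = FALSE]
  if (config$periodic) d <- min_image(d, config$cell)
  r <- sqrt(rowSums(d^2))
  inr <- r < rc
  a <- ii[keep][inr]; b <- jj[keep][inr]
  d <- d[inr, , drop = FALSE]; r <- r[inr]
  nf <- params$n_features; nj <- params$n_radial
  mt <- .moment_table(params$L)
  nets <- object$nets
  sc <- if (is.null(object$feature_scale)) rep(1, nf) else object$feature_scale
  F_out <- matrix(0, n, 3)
  if (!length(a)) return(F_out)

  cb <- params$embed[config$elements[b]]
  fc <- 0.5 * (cos(pi * r / rc) + 1)
  dfc <- -0.5 * pi / rc * sin(pi * r / rc)
  gmat <- exp(-params$eta * (outer(r, params$centers, "-"))^2)
  dgmat <- gmat * (-2 * params$eta * outer(r, params$centers, "-"))
  gcut <- gmat * fc
  dgcut <- dgmat * fc + gmat * dfc
  u <- d / r

  na <- nrow(mt)
  Pm <- matrix(1, length(a), na)
  for (q in seq_len(na))
    Pm[, q] <- d[, 1]^mt$ax[q] * d[, 2]^mt$ay[q] * d[, 3]^mt$az[q]
  # S[atom, alpha, j]
  S <- array(0, c(n, na, nj))
  for (q in seq_len(na))
    S[, q, ] <- .rowsum_pad(cb * Pm[, q] * gcut, a, n)
  feats <- matrix(0, n, nf)
  for (q in seq_len(na)) {
    cols <- mt$l[q] * nj + seq_len(nj)
    feats[, cols] <- feats[, cols] + mt$w[q] * S[, q, ]^2
  }
  # batched network gradients per element
  G <- matrix(0, n, nf)
  for (e in unique(config$elements)) {
    sel <- which(config$elements == e)
    out <- .net_g_batch(nets[[e]],
                        sweep(feats[sel, , drop = FALSE], 2, sc, "/"))
    G[sel, ] <- sweep(out$G, 2, sc, "/")
  }
  # Y[a, (alpha, j)] = 2 w_alpha S * G at the matching feature column
  for (q in seq_len(na)) {
    cols <- mt$l[q] * nj + seq_len(nj)
    Yq <- 2 * mt$w[q] * S[, q, ] * G[, cols, drop = FALSE]   # n x nj
    Ya <- Yq[a, , drop = FALSE]
    ax <- mt$ax[q]; ay <- mt$ay[q]; az <- mt$az[q]
    for (k in 1:3) {
      dP <- switch(k,
        if (ax > 0) ax * .safe_pow(d[, 1], ax - 1) * d[, 2]^ay * d[, 3]^az
        else numeric(length(a)),
        if (ay > 0) ay * d[, 1]^ax * .safe_pow(d[, 2], ay - 1) * d[, 3]^az
        else numeric(length(a)),
        if (az > 0) az * d[, 1]^ax * d[, 2]^ay * .safe_pow(d[, 3], az - 1)
        else numeric(length(a)))
      dS <- cb * (dP * gcut + Pm[, q] * u[, k] * dgcut)       # pairs x nj
      coef <- rowSums(dS * Ya)
      # force = -sum_a g_a df_a/dx: df_a/dx_b = dS, df_a/dx_a = -sum dS
      F_out[, k] <- F_out[, k] - .rowsum_pad(coef, b, n) +
        .rowsum_pad(coef, a, n)
    }
  }
  F_out
}
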