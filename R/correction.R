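#' Construct a centroid-force training record
#'
#' A single training example: a centroid geometry with its converged
#' mean bead force and the classical force at the same geometry.  The
#' learning target is their difference, the quantum centroid force
#' correction.  [sample_fixed_centroid()] produces these from PIMD;
#' this constructor also lets exact references (the 1D oracle) or
#' synthetic teachers provide labels.
#'
#' @param geometry a [molecular_configuration()].
#' @param mean_force N x 3 mean bead force, kJ/mol/Angstrom.
#' @param classical_force N x 3 classical force at the geometry.
#' @param force_sem N x 3 standard errors (0 for exact references).
#' @param meta metadata list.
#' @return a \code{centroid_force_record}.
#' @export
centroid_force_record <- function(geometry, mean_force, classical_force,
                                  force_sem = 0 * mean_force,
                                  meta = list()) {
  mean_force <- as.matrix(mean_force); classical_force <- as.matrix(classical_force)
  stopifnot(all(dim(mean_force) == c(n_atoms(geometry), 3)),
            all(dim(classical_force) == dim(mean_force)),
            all(is.finite(mean_force)), all(is.finite(classical_force)))
  structure(list(geometry = geometry, mean_force = mean_force,
                 force_sem = as.matrix(force_sem),
                 classical_force = classical_force,
                 delta_force = mean_force - classical_force,
                 converged = TRUE, meta = meta),
            class = "centroid_force_record")
}

# --- feed-forward net internals --------------------------------------------
# Two tanh hidden layers, linear scalar output.  The model scalar is
# defined only up to a constant (forces carry no offset information),
# so the output bias is fixed at zero and excluded from training.

.net_random <- function(nf, hidden, rng, scale = 1) {
  n1 <- hidden[1]; n2 <- hidden[2]
  list(W1 = matrix(rng_gauss(rng, n1 * nf) * scale / sqrt(nf), n1, nf),
       b1 = rng_gauss(rng, n1) * 0.1,
       W2 = matrix(rng_gauss(rng, n2 * n1) * scale / sqrt(n1), n2, n1),
       b2 = rng_gauss(rng, n2) * 0.1,
       w3 = rng_gauss(rng, n2) / sqrt(n2))
}

.net_npar <- function(net)
  length(net$W1) + length(net$b1) + length(net$W2) + length(net$b2) +
  length(net$w3)

.net_pack <- function(net)
  c(as.vector(net$W1), net$b1, as.vector(net$W2), net$b2, net$w3)

.net_unpack <- function(theta, nf, hidden) {
  n1 <- hidden[1]; n2 <- hidden[2]
  i <- 0
  take <- function(k) { out <- theta[(i + 1):(i + k)]; i <<- i + k; out }
  list(W1 = matrix(take(n1 * nf), n1, nf), b1 = take(n1),
       W2 = matrix(take(n2 * n1), n2, n1), b2 = take(n2), w3 = take(n2))
}

# feature gradient g = d(net)/d(features), plus intermediates
.net_g <- function(net, f) {
  z1 <- as.vector(net$W1 %*% f) + net$b1
  a1 <- tanh(z1); d1 <- 1 - a1^2
  z2 <- as.vector(net$W2 %*% a1) + net$b2
  a2 <- tanh(z2); d2 <- 1 - a2^2
  v2 <- d2 * net$w3
  w2tv2 <- as.vector(crossprod(net$W2, v2))
  v1 <- d1 * w2tv2
  g <- as.vector(crossprod(net$W1, v1))
  list(g = g, a1 = a1, d1 = d1, a2 = a2, d2 = d2, v1 = v1, v2 = v2,
       w2tv2 = w2tv2, u = sum(net$w3 * a2))
}

# d g / d theta (n_features x n_params), analytic.  The compiled
# kernel is the hot path; this R implementation is retained as the
# cross-checked reference.
.net_g_jac <- function(net, f) {
  net_g_jac_cpp(net$W1, net$b1, net$W2, net$b2, net$w3, f)
}

.net_g_jac_ref <- function(net, f) {
  st <- .net_g(net, f)
  n1 <- length(net$b1); n2 <- length(net$b2); nf <- length(f)
  dd1 <- -2 * st$a1 * st$d1
  dd2 <- -2 * st$a2 * st$d2
  W1t <- t(net$W1)                                   # nf x n1
  M1 <- sweep(W1t, 2, st$d1, "*")                    # W1' diag(d1)
  dg_dw3 <- M1 %*% t(sweep(net$W2, 1, st$d2, "*"))   # nf x n2
  dg_db2 <- M1 %*% t(sweep(net$W2, 1, dd2 * net$w3, "*"))
  # W2 blocks: d g / d W2[k, j] = v2[k] M1[, j] + a1[j] dg_db2[, k]
  dg_dW2 <- matrix(0, nf, n2 * n1)
  for (k in seq_len(n2))
    dg_dW2[, (0:(n1 - 1)) * n2 + k] <-
      st$v2[k] * M1 + outer(dg_db2[, k], st$a1)
  S <- crossprod(net$W2, sweep(net$W2, 1, dd2 * net$w3, "*"))  # n1 x n1
  dg_db1 <- sweep(W1t, 2, dd1 * st$w2tv2, "*") +
    W1t %*% (S * outer(st$d1, st$d1))
  # W1 blocks: d g / d W1[k, j] = delta_j v1[k] + f[j] dg_db1[, k]
  dg_dW1 <- matrix(0, nf, n1 * nf)
  If <- diag(nf)
  for (k in seq_len(n1))
    dg_dW1[, (0:(nf - 1)) * n1 + k] <-
      st$v1[k] * If + outer(dg_db1[, k], f)
  cbind(dg_dW1, dg_db1, dg_dW2, dg_db2, dg_dw3)
}

# --- dataset preparation ----------------------------------------------------

.prepare_dataset <- function(records, params, scale = NULL) {
  data <- lapply(records, function(rec) {
    cfg <- rec$geometry
    ft <- compute_features(cfg, params, gradients = TRUE)
    n <- n_atoms(cfg)
    # flatten per-atom gradients once: Gm[(i,k), q] reused every call
    atoms <- lapply(seq_len(n), function(a) {
      gr <- ft$grads[[a]]
      nidx <- length(gr$idx)
      list(idx = gr$idx, nidx = nidx,
           Gm = t(matrix(gr$grad, dim(gr$grad)[1], nidx * 3)),
           f = ft$features[a, ])
    })
    list(n = n, elements = cfg$elements, atoms = atoms,
         labels = as.vector(rec$delta_force))
  })
  if (is.null(scale)) {
    allf <- do.call(rbind, lapply(data, function(dc)
      do.call(rbind, lapply(dc$atoms, `[[`, "f"))))
    scale <- pmax(sqrt(colMeans(allf^2)), 1e-8)
  }
  for (i in seq_along(data)) {
    for (a in seq_len(data[[i]]$n)) {
      data[[i]]$atoms[[a]]$f <- data[[i]]$atoms[[a]]$f / scale
      data[[i]]$atoms[[a]]$Gm <-
        sweep(data[[i]]$atoms[[a]]$Gm, 2, scale, "/")
    }
  }
  attr(data, "feature_scale") <- scale
  data
}

.predict_config_forces <- function(nets, data_cfg) {
  n <- data_cfg$n
  F <- matrix(0, n, 3)
  single <- length(nets) == 1L
  for (a in seq_len(n)) {
    at <- data_cfg$atoms[[a]]
    net <- if (single) nets[[1]] else nets[[data_cfg$elements[a]]]
    g <- .net_g(net, at$f)$g
    contrib <- matrix(at$Gm %*% g, at$nidx, 3)
    F[at$idx, ] <- F[at$idx, ] - contrib
  }
  F
}

#' Train the quantum force-correction model
#'
#' Fits per-element feed-forward networks whose summed atomic scalar
#' has, as its negative gradient, the quantum centroid force
#' correction: a pure force-matching objective (no energy labels
#' exist, so the scalar is defined up to a constant).  Training is the
#' hybrid extreme-learning-machine / Levenberg-Marquardt scheme:
#' stage one fixes random hidden weights and solves the output layer
#' by (ridge-regularised) linear least squares, which is exact because
#' predicted forces are linear in the output weights; stage two
#' refines all weights with Levenberg-Marquardt using analytic
#' Jacobians.  Deterministic for a given seed.
#'
#' @param records list of \code{centroid_force_record}s (>= 2), or a
#'   \code{training_set}.
#' @param params a [descriptor_params()] / [descriptor_params_1d()].
#' @param hidden hidden-layer sizes (default c(20, 20)).
#' @param seed integer seed for the random hidden weights.
#' @param lm_maxit maximum Levenberg-Marquardt iterations (0 skips the
#'   LM stage).
#' @param loss_tol convergence criterion on the loss, defined as the
#'   RMS force residual in kJ/(mol Angstrom) (default 0.1).
#' @param ridge ridge parameter for the ELM linear solve (relative to
#'   the mean diagonal of the normal matrix).
#' @param decay Tikhonov weight-decay strength in the LM stage
#'   (appended residual rows sqrt(decay)*rms(labels)*theta); also
#'   guarantees the LM problem stays overdetermined.
#' @param init_scale scale of the random hidden weights.
#' @return an object of class \code{correction_model} with
#'   \code{print}, \code{summary}, \code{coef} and \code{predict}
#'   methods.
#' @seealso [predict.correction_model()], [sample_fixed_centroid()]
#' @export
train_correction <- function(records, params, hidden = c(20, 20), seed = 1,
                             lm_maxit = 60, loss_tol = 0.1, ridge = 1e-6,
                             decay = 1e-4, init_scale = 1) {
  if (inherits(records, "centroid_force_record")) records <- list(records)
  if (length(records) < 2) stop("need at least 2 training records")
  data <- .prepare_dataset(records, params)
  feature_scale <- attr(data, "feature_scale")
  elements <- params$elements
  nf <- params$n_features
  rng <- seeded_rng(seed)
  nets <- stats::setNames(
    lapply(elements, function(e) .net_random(nf, hidden, rng, init_scale)),
    elements)
  labels <- unlist(lapply(data, `[[`, "labels"))
  n_res <- length(labels)

  # --- stage 1: ELM (linear solve for the output layers) ---
  n2 <- hidden[2]
  X <- matrix(0, n_res, n2 * length(elements))
  off <- 0
  for (dc in data) {
    rows <- off + seq_len(3 * dc$n)
    for (a in seq_len(dc$n)) {
      e <- if (length(elements) == 1L) 1L else match(dc$elements[a], elements)
      at <- dc$atoms[[a]]
      net <- nets[[e]]
      st <- .net_g(net, at$f)
      M2 <- sweep(t(net$W1), 2, st$d1, "*") %*%
        t(sweep(net$W2, 1, st$d2, "*"))            # nf x n2, w3-independent
      blk <- -matrix_rows_accumulate(at$Gm %*% M2, at$idx, dc$n)
      cols <- (e - 1) * n2 + seq_len(n2)
      X[rows, cols] <- X[rows, cols] + blk
    }
    off <- off + 3 * dc$n
  }
  A <- crossprod(X)
  A <- A + ridge * mean(diag(A)) * diag(ncol(X))
  w3_all <- solve(A, crossprod(X, labels))
  for (e in seq_along(elements))
    nets[[e]]$w3 <- w3_all[(e - 1) * n2 + seq_len(n2)]
  loss_trace <- .rms(unlist(lapply(data, function(dc)
    as.vector(.predict_config_forces(nets, dc)))) - labels)

  # --- stage 2: Levenberg-Marquardt on all weights ---
  if (lm_maxit > 0) {
    npar_e <- vapply(nets, .net_npar, 0L)
    theta0 <- unlist(lapply(nets, .net_pack), use.names = FALSE)
    unpack_all <- function(theta) {
      out <- nets; i <- 0
      for (e in seq_along(elements)) {
        out[[e]] <- .net_unpack(theta[i + seq_len(npar_e[e])], nf, hidden)
        i <- i + npar_e[e]
      }
      out
    }
    trace_env <- new.env(); trace_env$loss <- loss_trace
    wreg <- sqrt(decay) * .rms(labels)      # weight-decay rows
    fn <- function(theta) {
      nets_t <- unpack_all(theta)
      pred <- unlist(lapply(data, function(dc)
        as.vector(.predict_config_forces(nets_t, dc))))
      r <- pred - labels
      trace_env$loss <- c(trace_env$loss, .rms(r))
      c(r, wreg * theta)
    }
    jac <- function(theta) {
      nets_t <- unpack_all(theta)
      J <- matrix(0, n_res, sum(npar_e))
      col_off <- c(0, cumsum(npar_e))
      off <- 0
      for (dc in data) {
        for (a in seq_len(dc$n)) {
          e <- if (length(elements) == 1L) 1L
               else match(dc$elements[a], elements)
          at <- dc$atoms[[a]]
          dg <- .net_g_jac(nets_t[[e]], at$f)       # nf x npar_e
          blk <- -matrix_rows_accumulate(at$Gm %*% dg, at$idx, dc$n)
          cols <- col_off[e] + seq_len(npar_e[e])
          rows <- off + seq_len(3 * dc$n)
          J[rows, cols] <- J[rows, cols] + blk
        }
        off <- off + 3 * dc$n
      }
      rbind(J, wreg * diag(length(theta)))
    }
    ctl <- minpack.lm::nls.lm.control(maxiter = lm_maxit,
                                      ftol = 1e-12, ptol = 1e-12)
    fit <- minpack.lm::nls.lm(par = theta0, fn = fn, jac = jac,
                              control = ctl)
    nets_lm <- unpack_all(fit$par)
    final_lm <- .rms(unlist(lapply(data, function(dc)
      as.vector(.predict_config_forces(nets_lm, dc)))) - labels)
    if (final_lm <= loss_trace[length(loss_trace)]) {
      nets <- nets_lm
      loss_trace <- c(trace_env$loss, final_lm)
    } else {
      warning("LM stage did not improve on the ELM solution; keeping ELM")
    }
  }

  final_loss <- .rms(unlist(lapply(data, function(dc)
    as.vector(.predict_config_forces(nets, dc)))) - labels)
  structure(list(params = params, hidden = hidden, nets = nets,
                 elements = elements, feature_scale = feature_scale,
                 meta = list(seed = seed, n_records = length(records),
                             n_residuals = n_res, loss = final_loss,
                             loss_tol = loss_tol,
                             converged = final_loss <= loss_tol,
                             loss_trace = loss_trace)),
            class = "correction_model")
}

.rms <- function(x) sqrt(mean(x^2))

# scatter-accumulate row blocks of a (nidx*3) x m matrix into a
# (3n) x m matrix ordered (atom, component) column-major like
# as.vector(F)
matrix_rows_accumulate <- function(blk, idx, n) {
  out <- matrix(0, 3 * n, ncol(blk))
  nidx <- length(idx)
  rows <- c(idx, n + idx, 2 * n + idx)  # (i,k) -> (k-1)*n + i
  ord <- as.vector(outer(seq_len(nidx), (0:2) * nidx, "+"))
  out[rows, ] <- out[rows, ] + blk[ord, ]
  out
}

#' Predict quantum force corrections
#'
#' Evaluates the learned correction forces (the exact negative
#' gradient of the model's summed atomic scalar) on a configuration.
#' Cost is linear in atom count at fixed neighbour density, so the
#' correction runs at classical-force cost.
#'
#' @param object a \code{correction_model}.
#' @param config a [molecular_configuration()].
#' @param ... unused.
#' @return N x 3 matrix of correction forces, kJ/(mol Angstrom).
#' @export
predict.correction_model <- function(object, config, ...) {
  if (object$params$mode == "environment")
    return(.predict_env_forces(object, config))
  ft <- compute_features(config, object$params, gradients = TRUE)
  n <- n_atoms(config)
  miss <- setdiff(unique(config$elements), object$elements)
  if (object$params$mode == "environment" && length(miss))
    stop("model not trained for element(s): ", paste(miss, collapse = ", "))
  F <- matrix(0, n, 3)
  sc <- if (is.null(object$feature_scale)) 1 else object$feature_scale
  for (a in seq_len(n)) {
    net <- if (object$params$mode == "coordinate") object$nets[[1]]
           else object$nets[[config$elements[a]]]
    gr <- ft$grads[[a]]
    g <- .net_g(net, ft$features[a, ] / sc)$g / sc
    contrib <- matrix(t(matrix(gr$grad, dim(gr$grad)[1],
                               length(gr$idx) * 3)) %*% g,
                      length(gr$idx), 3)
    F[gr$idx, ] <- F[gr$idx, ] - contrib
  }
  F
}

#' Model scalar (correction potential) at a configuration
#'
#' The summed atomic scalar whose negative gradient is the predicted
#' correction force; defined up to an additive constant.
#'
#' @inheritParams predict.correction_model
#' @export
correction_scalar <- function(object, config) {
  ft <- compute_features(config, object$params, gradients = FALSE)
  sc <- if (is.null(object$feature_scale)) 1 else object$feature_scale
  tot <- 0
  for (a in seq_len(n_atoms(config))) {
    net <- if (object$params$mode == "coordinate") object$nets[[1]]
           else object$nets[[config$elements[a]]]
    tot <- tot + .net_g(net, ft$features[a, ] / sc)$u
  }
  tot
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(paste0("<correction_model: %s descriptors, hidden %s, ",
                     "elements %s>\n"),
              x$params$mode, paste(x$hidden, collapse = "x"),
              paste(x$elements, collapse = ",")))
  cat(sprintf("  training loss (RMS force residual): %.4g kJ/mol/A (%s)\n",
              x$meta$loss,
              if (x$meta$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.correction_model <- function(object, ...) {
  cat(sprintf("Correction model trained on %d records (%d force residuals)\n",
              object$meta$n_records, object$meta$n_residuals))
  cat(sprintf("  descriptor: %s, %d features\n", object$params$mode,
              object$params$n_features))
  cat(sprintf("  final loss %.4g kJ/mol/A; tolerance %.4g; %s\n",
              object$meta$loss, object$meta$loss_tol,
              if (object$meta$converged) "converged" else "NOT converged"))
  cat(sprintf("  loss trace: %s\n",
              paste(signif(utils::head(object$meta$loss_trace, 8), 3),
                    collapse = " -> ")))
  invisible(object)
}

#' @export
coef.correction_model <- function(object, ...)
  lapply(object$nets, .net_pack)

#' Random correction model (synthetic teacher)
#'
#' Draws a correction model with random weights, used as a synthetic
#' teacher in closure tests (labels it generates are exactly
#' representable by the architecture).
#'
#' @param params descriptor parameters.
#' @param hidden hidden-layer sizes.
#' @param seed integer seed.
#' @param scale weight scale (also applied to the output layer).
#' @param reference optional list of configurations used to set the
#'   teacher's feature normalization (without it, raw descriptor
#'   magnitudes can saturate the network and give needlessly rough
#'   synthetic targets).
#' @return a \code{correction_model}.
#' @export
random_correction_model <- function(params, hidden = c(20, 20), seed = 1,
                                    scale = 1, reference = NULL) {
  feature_scale <- NULL
  if (!is.null(reference)) {
    allf <- do.call(rbind, lapply(reference, function(cfg)
      compute_features(cfg, params)$features))
    feature_scale <- pmax(sqrt(colMeans(allf^2)), 1e-8)
  }
  rng <- seeded_rng(seed)
  nets <- stats::setNames(
    lapply(params$elements, function(e) {
      net <- .net_random(params$n_features, hidden, rng, scale)
      net$w3 <- net$w3 * scale
      net
    }), params$elements)
  structure(list(params = params, hidden = hidden, nets = nets,
                 elements = params$elements, feature_scale = feature_scale,
                 meta = list(seed = seed, n_records = 0, n_residuals = 0,
                             loss = NA, loss_tol = NA, converged = NA,
                             loss_trace = numeric())),
            class = "correction_model")
}

# export for the compiled 1D propagator
.corr_as_md1d <- function(model) {
  stopifnot(model$params$mode == "coordinate")
  net <- model$nets[[1]]
  W1 <- if (is.null(model$feature_scale)) net$W1
        else sweep(net$W1, 2, model$feature_scale, "/")  # fold scaling in
  list(centers = model$params$centers, width = model$params$width,
       W1 = W1, b1 = net$b1, W2 = net$W2, b2 = net$b2, w3 = net$w3)
}
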