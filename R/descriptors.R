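#' Atomic-environment descriptor parameters
#'
#' Features follow the embedded-atom scheme: for each atom, squared
#' embedded densities built from Cartesian-moment-weighted sums of
#' Gaussian-type orbitals over neighbours within a cutoff,
#' \deqn{f_{a,(l,j)} = \sum_{|\alpha| = l} \binom{l}{\alpha}
#'   \Big[\sum_{b \ne a} c_{e(b)}\, \Delta_x^{\alpha_x}
#'   \Delta_y^{\alpha_y} \Delta_z^{\alpha_z}\,
#'   e^{-\eta (r_b - r_j)^2} f_c(r_b)\Big]^2,}
#' with a cosine cutoff function f_c making every feature C^1 at the
#' cutoff.  The features are invariant under rotation, translation and
#' permutation of identical elements, and identically zero for an atom
#' with no neighbours.
#'
#' One-dimensional model systems (a single atom in an external
#' potential, so no translation-invariant environment exists) instead
#' use a coordinate basis of Gaussians along the active coordinate;
#' see [descriptor_params_1d()].
#'
#' @param cutoff environment cutoff r_c, Angstrom (default 4).
#' @param L maximum angular momentum (default 2).
#' @param n_radial number of radial Gaussian-type orbitals (default
#'   11), with centres spread evenly on [0, cutoff].
#' @param eta Gaussian width parameter, 1/Angstrom^2; default
#'   1/(2 dr^2) for centre spacing dr.
#' @param elements species the descriptor covers; per-element embedding
#'   coefficients are fixed, distinct constants in this order.
#' @return object of class \code{descriptor_params}.
#' @export
descriptor_params <- function(cutoff = 4, L = 2, n_radial = 11, eta = NULL,
                              elements = c("H", "O")) {
  centers <- seq(0, cutoff, length.out = n_radial)
  dr <- centers[2] - centers[1]
  if (is.null(eta)) eta <- 1 / (2 * dr^2)
  emb <- 1 + 0.4 * (seq_along(elements) - 1)
  names(emb) <- elements
  structure(list(mode = "environment", cutoff = cutoff, L = L,
                 n_radial = n_radial, centers = centers, eta = eta,
                 elements = elements, embed = emb,
                 n_features = n_radial * (L + 1)),
            class = "descriptor_params")
}

#' @rdname descriptor_params
#' @param xlo,xhi range of the coordinate basis, Angstrom.
#' @param n_basis number of Gaussian basis functions.
#' @param width Gaussian width (standard deviation); defaults to the
#'   centre spacing.
#' @export
descriptor_params_1d <- function(xlo = -2, xhi = 2, n_basis = 11,
                                 width = NULL) {
  centers <- seq(xlo, xhi, length.out = n_basis)
  if (is.null(width)) width <- centers[2] - centers[1]
  structure(list(mode = "coordinate", centers = centers, width = width,
                 elements = "coord", n_features = n_basis),
            class = "descriptor_params")
}

#' @export
print.descriptor_params <- function(x, ...) {
  if (x$mode == "environment")
    cat(sprintf(paste0("<descriptor_params: environment mode, r_c=%g A, ",
                       "L=%d, %d GTOs, %d features, elements %s>\n"),
                x$cutoff, x$L, x$n_radial, x$n_features,
                paste(x$elements, collapse = ",")))
  else
    cat(sprintf("<descriptor_params: coordinate mode, %d Gaussians on [%g, %g] A>\n",
                length(x$centers), min(x$centers), max(x$centers)))
  invisible(x)
}

# multinomial Cartesian moment table up to L
.moment_table <- function(L) {
  a <- expand.grid(ax = 0:L, ay = 0:L, az = 0:L)
  a <- a[rowSums(a) <= L, ]
  a$l <- rowSums(a[, 1:3])
  a$w <- factorial(a$l) / (factorial(a$ax) * factorial(a$ay) * factorial(a$az))
  a[order(a$l), ]
}

#' Compute per-atom descriptor features (and position gradients)
#'
#' @param config a [molecular_configuration()].
#' @param params a [descriptor_params()] or [descriptor_params_1d()].
#' @param gradients also return feature gradients with respect to
#'   atomic positions (needed for force prediction and training).
#' @return list with \code{features} (N x n_features matrix) and, if
#'   requested, \code{grads}: per atom a list with \code{idx} (atoms
#'   its features depend on) and \code{grad} (n_features x
#'   length(idx) x 3 array of d f_a / d x).
#' @export
compute_features <- function(config, params, gradients = FALSE) {
  if (params$mode == "coordinate")
    return(.features_1d(config, params, gradients))
  n <- n_atoms(config)
  miss <- setdiff(unique(config$elements), params$elements)
  if (length(miss))
    stop("descriptor not parameterized for element(s): ",
         paste(miss, collapse = ", "))
  if (config$periodic && params$cutoff > min(config$cell) / 2 + 1e-12)
    stop("descriptor cutoff exceeds half the shortest box edge")
  mt <- .moment_table(params$L)
  nf <- params$n_features
  nj <- params$n_radial
  feats <- matrix(0, n, nf)
  grads <- if (gradients) vector("list", n) else NULL
  pos <- config$positions
  emb <- params$embed[config$elements]
  rc <- params$cutoff
  for (a in seq_len(n)) {
    d <- sweep(pos, 2, pos[a, ])
    if (config$periodic) d <- min_image(d, config$cell)
    r <- sqrt(rowSums(d^2))
    nb <- which(r < rc & seq_len(n) != a)
    if (!length(nb)) {
      if (gradients) grads[[a]] <- list(idx = a,
                                        grad = array(0, c(nf, 1, 3)))
      next
    }
    dnb <- d[nb, , drop = FALSE]; rnb <- r[nb]; cb <- emb[nb]
    fc <- 0.5 * (cos(pi * rnb / rc) + 1)
    dfc <- -0.5 * pi / rc * sin(pi * rnb / rc)
    gmat <- exp(-params$eta * (outer(rnb, params$centers, "-"))^2)  # nb x nj
    dgmat <- gmat * (-2 * params$eta * outer(rnb, params$centers, "-"))
    gcut <- gmat * fc                      # orbital radial part with cutoff
    dgcut <- dgmat * fc + gmat * dfc       # d/dr of the same
    nb_n <- length(nb)
    # Cartesian moments P_alpha per neighbour, and their gradients
    Pm <- matrix(1, nb_n, nrow(mt))
    for (q in seq_len(nrow(mt)))
      Pm[, q] <- dnb[, 1]^mt$ax[q] * dnb[, 2]^mt$ay[q] * dnb[, 3]^mt$az[q]
    # S[alpha, j] = sum_b c_b P_alpha(b) gcut(b, j)
    S <- crossprod(Pm * cb, gcut)          # n_alpha x nj
    fa <- numeric(nf)
    for (q in seq_len(nrow(mt))) {
      l <- mt$l[q]
      cols <- l * nj + seq_len(nj)
      fa[cols] <- fa[cols] + mt$w[q] * S[q, ]^2
    }
    feats[a, ] <- fa
    if (gradients) {
      idx <- c(nb, a)
      G <- array(0, c(nf, length(idx), 3))
      u <- dnb / rnb                        # unit vectors, nb x 3
      for (q in seq_len(nrow(mt))) {
        l <- mt$l[q]
        cols <- l * nj + seq_len(nj)
        # dP_alpha/d(x_b): derivative of the monomial in each component
        ax <- mt$ax[q]; ay <- mt$ay[q]; az <- mt$az[q]
        dP <- cbind(
          if (ax > 0) ax * .safe_pow(dnb[, 1], ax - 1) *
            dnb[, 2]^ay * dnb[, 3]^az else rep(0, nb_n),
          if (ay > 0) ay * dnb[, 1]^ax *
            .safe_pow(dnb[, 2], ay - 1) * dnb[, 3]^az else rep(0, nb_n),
          if (az > 0) az * dnb[, 1]^ax * dnb[, 2]^ay *
            .safe_pow(dnb[, 3], az - 1) else rep(0, nb_n))
        for (k in 1:3) {
          # dS[alpha,j]/dx_{b,k} = c_b [dP g + P u_k dg]
          dS <- cb * (dP[, k] * gcut + Pm[, q] * u[, k] * dgcut)  # nb x nj
          contrib <- 2 * mt$w[q] * t(dS) * S[q, ]                 # nj x nb
          G[cols, seq_len(nb_n), k] <- G[cols, seq_len(nb_n), k] + contrib
          G[cols, nb_n + 1L, k] <- G[cols, nb_n + 1L, k] - rowSums(contrib)
        }
      }
      grads[[a]] <- list(idx = idx, grad = G)
    }
  }
  list(features = feats, grads = grads)
}

.safe_pow <- function(x, p) if (p == 0) rep(1, length(x)) else x^p

.features_1d <- function(config, params, gradients) {
  x <- config$positions[1, 1]
  d <- (x - params$centers) / params$width
  phi <- exp(-0.5 * d^2)
  feats <- matrix(phi, 1, length(phi))
  grads <- NULL
  if (gradients) {
    G <- array(0, c(length(phi), 1, 3))
    G[, 1, 1] <- -d / params$width * phi
    grads <- list(list(idx = 1L, grad = G))
  }
  list(features = feats, grads = grads)
}
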