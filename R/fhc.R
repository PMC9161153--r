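#' Second-order Feynman-Hibbs pair correction
#'
#' For a pairwise, spherically symmetric potential the Gaussian-
#' smearing (Feynman-Hibbs) effective potential truncated at second
#' order is
#' \deqn{u_{FH}(r) = u(r) + \frac{\beta\hbar^2}{24\mu}
#'   \left[u''(r) + \frac{2}{r} u'(r)\right],}
#' with mu the reduced mass of the pair.  The bracket is the radial
#' Laplacian of u, so any pure Coulomb pair has an identically zero
#' correction.
#'
#' @param potential a pairwise \code{potential_surface}.
#' @param pair character vector of two species labels.
#' @param r separation(s), Angstrom.
#' @param T temperature, K.
#' @param masses optional named per-element masses (amu); defaults to
#'   the built-in table plus any masses the potential declares.
#' @return list with \code{u_fh}, \code{correction} (both kJ/mol) and
#'   \code{mu} (amu).
#' @examples
#' pot <- lj_coulomb_cluster(list(H = list(eps = 0, sigma = 1, charge = 0.5)))
#' fhc_pair_correction(pot, c("H", "H"), 2.5, 300)$correction  # exactly 0
#' @export
fhc_pair_correction <- function(potential, pair, r, T, masses = NULL) {
  d <- pair_derivatives(potential, pair, r)
  mi <- .species_mass(potential, pair[1], masses)
  mj <- .species_mass(potential, pair[2], masses)
  mu <- 1 / (1 / mi + 1 / mj)
  corr <- beta_of(T) * .const$hbar^2 / (24 * mass_to_energy_units(mu)) *
    (d$d2u + 2 * d$du / r)
  list(u_fh = d$u + corr, correction = corr, mu = mu)
}

.species_mass <- function(potential, species, masses = NULL) {
  if (!is.null(masses) && species %in% names(masses))
    return(as.numeric(masses[[species]]))
  if (!is.null(potential$species) &&
      !is.null(potential$species[[species]]$mass))
    return(potential$species[[species]]$mass)
  if (!is.null(potential$element) && identical(potential$element, species) &&
      !is.null(potential$mass))
    return(potential$mass)
  tab <- element_masses()
  if (species %in% names(tab)) return(unname(tab[species]))
  stop("no mass known for species '", species, "'")
}

#' One-dimensional Feynman-Hibbs effective potential by convolution
#'
#' Convolves a tabulated potential with the variational Gaussian
#' kernel of variance hbar^2 / 12 m k T.  The kernel is normalized on
#' the grid (a constant potential maps to itself exactly); output
#' points closer than \code{n_sigma} kernel widths to a grid edge are
#' flagged invalid because the convolution is truncated there.
#'
#' @param x uniform grid, Angstrom.
#' @param U potential values on \code{x}, kJ/mol.
#' @param m mass, amu.
#' @param T temperature, K.
#' @param n_sigma validity margin in kernel standard deviations
#'   (default 7, leaving < 1e-10 kernel mass outside).
#' @return data frame with columns \code{x}, \code{K} (effective
#'   potential) and \code{valid}.
#' @export
fhc_convolve_1d <- function(x, U, m, T, n_sigma = 7) {
  if (length(x) != length(U)) stop("x and U lengths differ")
  dx <- diff(x)
  if (max(abs(dx - dx[1])) > 1e-9 * abs(dx[1])) stop("grid must be uniform")
  sigma2 <- fhc_width(T, m)
  sigma <- sqrt(sigma2)
  if (sigma < dx[1])
    warning("kernel narrower than the grid spacing; convolution is ",
            "effectively the identity at this resolution")
  span <- x[length(x)] - x[1]
  if (span < 2 * n_sigma * sigma)
    stop("grid too narrow for the Feynman-Hibbs kernel at this ",
         "temperature: need a span of at least ", 2 * n_sigma,
         " kernel widths (", signif(2 * n_sigma * sigma, 4), " Angstrom)")
  # dense quadrature with a per-row normalized kernel
  D <- outer(x, x, function(a, b) exp(-(a - b)^2 / (2 * sigma2)))
  K <- as.vector(D %*% U) / rowSums(D)
  valid <- x >= x[1] + n_sigma * sigma & x <= x[length(x)] - n_sigma * sigma
  data.frame(x = x, K = K, valid = valid)
}
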