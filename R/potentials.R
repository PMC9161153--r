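#' Potential energy surfaces for the built-in model systems
#'
#' Every model system implements the same contract: [evaluate()] maps a
#' [molecular_configuration()] to an energy (kJ/mol) and exact
#' analytic forces (kJ/mol/Angstrom, the negative energy gradient).
#' Pairwise kinds additionally expose analytic radial derivatives
#' through [pair_derivatives()], which the Feynman-Hibbs correction
#' needs.
#'
#' One-dimensional model potentials are represented as a single atom
#' whose x coordinate is the active degree of freedom, so the same
#' sampler code paths apply to them.
#'
#' @name potentials
NULL

.new_potential <- function(kind, params, pairwise = FALSE) {
  structure(c(list(kind = kind, pairwise = pairwise), params),
            class = c(kind, "potential_surface"))
}

#' @export
print.potential_surface <- function(x, ...) {
  cat(sprintf("<potential_surface '%s'%s>\n", x$kind,
              if (isTRUE(x$pairwise)) " (pairwise)" else ""))
  invisible(x)
}

#' One-dimensional model potentials
#'
#' \code{harmonic1d}: U = k x^2 / 2.  \code{quartic1d}: U = c x^4 / 4.
#' \code{morse1d}: U = D (1 - exp(-a x))^2.  Each acts on the x
#' coordinate of a single atom.
#'
#' @param k harmonic force constant, kJ/mol/Angstrom^2.  Alternatively
#'   give \code{omega_cm1} (a wavenumber) and the force constant is
#'   m omega^2 for the stated mass.
#' @param mass atom mass in amu (used for \code{omega_cm1} and by
#'   samplers via the configuration).
#' @param element species label for the single atom.
#' @param omega_cm1 optional intrinsic frequency in cm^-1.
#' @return a \code{potential_surface}.
#' @examples
#' pot <- harmonic1d(k = 2)          # U(2 Angstrom) = 4 kJ/mol
#' cfg <- config_1d(2, element = "H")
#' evaluate(pot, cfg)
#' @export
harmonic1d <- function(k = NULL, mass = 1.008, element = "H",
                       omega_cm1 = NULL) {
  if (is.null(k)) {
    if (is.null(omega_cm1)) stop("give k or omega_cm1")
    k <- mass_to_energy_units(mass) * cm1_to_angular(omega_cm1)^2
  }
  .new_potential("harmonic1d", list(k = k, mass = mass, element = element))
}

#' @rdname harmonic1d
#' @param c quartic coefficient, kJ/mol/Angstrom^4.
#' @export
quartic1d <- function(c = 10, mass = 1.008, element = "H")
  .new_potential("quartic1d", list(c = c, mass = mass, element = element))

#' @rdname harmonic1d
#' @param D well depth, kJ/mol.
#' @param a range parameter, 1/Angstrom.
#' @export
morse1d <- function(D = 40, a = 1.5, mass = 1.008, element = "H")
  .new_potential("morse1d", list(D = D, a = a, mass = mass, element = element))

#' Single-atom configuration for 1D model potentials
#'
#' @param x position along the active coordinate (Angstrom).
#' @param element species label.
#' @param mass mass in amu (defaults to the element table).
#' @export
config_1d <- function(x, element = "H", mass = NULL) {
  molecular_configuration(element, matrix(c(x, 0, 0), 1),
                          masses = if (is.null(mass)) NULL else mass)
}

# closed-form 1D energy/derivative, shared by samplers and the oracle
u1d <- function(pot, x) {
  switch(pot$kind,
    harmonic1d = 0.5 * pot$k * x^2,
    quartic1d  = 0.25 * pot$c * x^4,
    morse1d    = pot$D * (1 - exp(-pot$a * x))^2,
    free1d     = 0 * x,
    stop("not a 1D potential: ", pot$kind))
}

du1d <- function(pot, x) {
  switch(pot$kind,
    harmonic1d = pot$k * x,
    quartic1d  = pot$c * x^3,
    morse1d    = 2 * pot$D * pot$a * exp(-pot$a * x) * (1 - exp(-pot$a * x)),
    free1d     = 0 * x,
    stop("not a 1D potential: ", pot$kind))
}

is_1d_potential <- function(pot)
  pot$kind %in% c("harmonic1d", "quartic1d", "morse1d", "free1d")

#' @rdname harmonic1d
#' @export
free1d <- function(mass = 1.008, element = "H")
  .new_potential("free1d", list(mass = mass, element = element))

#' Lennard-Jones + point-charge cluster potential
#'
#' Non-periodic pair potential: 4 eps [(sigma/r)^12 - (sigma/r)^6] with
#' Lorentz-Berthelot mixing between species, plus bare Coulomb
#' q_i q_j / (4 pi eps0 r) from fixed per-species point charges.
#' Selected atom pairs can be excluded (e.g. bonded neighbours).
#'
#' @param species named list; each entry a list with \code{eps}
#'   (kJ/mol), \code{sigma} (Angstrom), \code{charge} (e) and
#'   optionally \code{mass} (amu).
#' @param exclusions optional 2-column integer matrix of atom-index
#'   pairs to skip.
#' @export
lj_coulomb_cluster <- function(species, exclusions = NULL) {
  for (s in names(species)) {
    p <- species[[s]]
    if (is.null(p$eps) || is.null(p$sigma) || is.null(p$charge))
      stop("species '", s, "' needs eps, sigma and charge")
  }
  if (!is.null(exclusions)) exclusions <- matrix(as.integer(exclusions),
                                                 ncol = 2)
  .new_potential("lj_coulomb_cluster",
                 list(species = species, exclusions = exclusions),
                 pairwise = TRUE)
}

#' Periodic monoatomic pair fluid
#'
#' A single-species Lennard-Jones fluid under the minimum-image
#' convention with a shifted-force cutoff, so energy and forces are
#' continuous at the cutoff and forces remain the exact negative
#' gradient.
#'
#' @param eps,sigma LJ parameters (kJ/mol, Angstrom).
#' @param cutoff cutoff radius (Angstrom); must not exceed half the
#'   shortest box edge of any configuration it is evaluated on.
#' @param element species label (declare its mass here).
#' @param mass mass in amu for the toy species.
#' @export
periodic_pair_fluid <- function(eps = 1.0, sigma = 2.8, cutoff = 3 * sigma,
                                element = "X", mass = 2.016) {
  .new_potential("periodic_pair_fluid",
                 list(eps = eps, sigma = sigma, cutoff = cutoff,
                      element = element, mass = mass),
                 pairwise = TRUE)
}

#' Evaluate a potential on a configuration
#'
#' @param potential a \code{potential_surface}.
#' @param config a [molecular_configuration()].
#' @return list with \code{energy} (kJ/mol) and \code{forces}
#'   (N x 3 matrix, kJ/mol/Angstrom).
#' @export
evaluate <- function(potential, config) UseMethod("evaluate")

#' @export
evaluate.default <- function(potential, config)
  stop("no evaluator for kind '", potential$kind, "'")

.eval_1d <- function(potential, config) {
  x <- config$positions[1, 1]
  F <- matrix(0, n_atoms(config), 3)
  F[1, 1] <- -du1d(potential, x)
  list(energy = u1d(potential, x), forces = F)
}

#' @export
evaluate.harmonic1d <- function(potential, config) .eval_1d(potential, config)
#' @export
evaluate.quartic1d <- function(potential, config) .eval_1d(potential, config)
#' @export
evaluate.morse1d <- function(potential, config) .eval_1d(potential, config)
#' @export
evaluate.free1d <- function(potential, config) .eval_1d(potential, config)

# --- pairwise machinery -----------------------------------------------------

.lb_mix <- function(pa, pb)
  list(eps = sqrt(pa$eps * pb$eps), sigma = 0.5 * (pa$sigma + pb$sigma))

.lj_u <- function(eps, sigma, r) {
  sr6 <- (sigma / r)^6
  4 * eps * (sr6^2 - sr6)
}
.lj_du <- function(eps, sigma, r) {
  sr6 <- (sigma / r)^6
  (-48 * eps * sr6^2 + 24 * eps * sr6) / r
}
.lj_d2u <- function(eps, sigma, r) {
  sr6 <- (sigma / r)^6
  (624 * eps * sr6^2 - 168 * eps * sr6) / r^2
}

# pair interaction table for a cluster configuration
.cluster_pairs <- function(potential, elements) {
  n <- length(elements)
  if (n < 2) return(NULL)
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  if (!is.null(potential$exclusions) && nrow(potential$exclusions)) {
    key <- paste(pmin(i, j), pmax(i, j))
    ex <- paste(pmin(potential$exclusions[, 1], potential$exclusions[, 2]),
                pmax(potential$exclusions[, 1], potential$exclusions[, 2]))
    keep <- !(key %in% ex)
    i <- i[keep]; j <- j[keep]
  }
  sp <- potential$species
  miss <- setdiff(unique(elements), names(sp))
  if (length(miss))
    stop("potential not parameterized for species: ",
         paste(miss, collapse = ", "))
  eps <- sig <- qq <- numeric(length(i))
  for (p in seq_along(i)) {
    mix <- .lb_mix(sp[[elements[i[p]]]], sp[[elements[j[p]]]])
    eps[p] <- mix$eps; sig[p] <- mix$sigma
    qq[p] <- sp[[elements[i[p]]]]$charge * sp[[elements[j[p]]]]$charge
  }
  list(i = i, j = j, eps = eps, sigma = sig, qq = qq)
}

#' @export
evaluate.lj_coulomb_cluster <- function(potential, config) {
  if (config$periodic)
    stop("lj_coulomb_cluster is a non-periodic (bare Coulomb) potential")
  pr <- .cluster_pairs(potential, config$elements)
  F <- matrix(0, n_atoms(config), 3)
  if (is.null(pr)) return(list(energy = 0, forces = F))
  d <- config$positions[pr$i, , drop = FALSE] -
       config$positions[pr$j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  u <- .lj_u(pr$eps, pr$sigma, r) + .const$coulomb * pr$qq / r
  du <- .lj_du(pr$eps, pr$sigma, r) - .const$coulomb * pr$qq / r^2
  fpair <- -du / r   # force magnitude / r, along d, acting on atom i
  fv <- d * fpair
  acc_i <- rowsum(fv, pr$i)
  F[as.integer(rownames(acc_i)), ] <- F[as.integer(rownames(acc_i)), ] + acc_i
  acc_j <- rowsum(fv, pr$j)
  F[as.integer(rownames(acc_j)), ] <- F[as.integer(rownames(acc_j)), ] - acc_j
  list(energy = sum(u), forces = F)
}

#' @export
evaluate.periodic_pair_fluid <- function(potential, config) {
  if (!config$periodic) stop("periodic_pair_fluid needs a periodic box")
  rc <- potential$cutoff
  if (rc > min(config$cell) / 2 + 1e-12)
    stop("cutoff exceeds half the shortest box edge")
  if (!all(config$elements == potential$element))
    stop("potential not parameterized for species: ",
         paste(setdiff(unique(config$elements), potential$element),
               collapse = ", "))
  out <- lj_fluid_eval(config$positions, config$cell, potential$eps,
                       potential$sigma, rc)
  list(energy = out$energy, forces = out$forces, virial = out$virial)
}

#' Analytic radial derivatives of a pairwise potential
#'
#' For pairwise kinds, returns u(r), u'(r) and u''(r) for a species
#' pair.  Needed by the second-order Feynman-Hibbs correction.
#'
#' @param potential pairwise \code{potential_surface}.
#' @param pair character vector of two species labels.
#' @param r separation(s), Angstrom (> 0).
#' @return list with vectors \code{u}, \code{du}, \code{d2u}.
#' @export
pair_derivatives <- function(potential, pair, r) UseMethod("pair_derivatives")

#' @export
pair_derivatives.default <- function(potential, pair, r)
  stop("'", potential$kind, "' is not a pairwise potential")

#' @export
pair_derivatives.lj_coulomb_cluster <- function(potential, pair, r) {
  if (any(r <= 0)) stop("r must be positive")
  sp <- potential$species
  if (!all(pair %in% names(sp)))
    stop("potential not parameterized for species: ",
         paste(setdiff(pair, names(sp)), collapse = ", "))
  mix <- .lb_mix(sp[[pair[1]]], sp[[pair[2]]])
  qq <- .const$coulomb * sp[[pair[1]]]$charge * sp[[pair[2]]]$charge
  list(u = .lj_u(mix$eps, mix$sigma, r) + qq / r,
       du = .lj_du(mix$eps, mix$sigma, r) - qq / r^2,
       d2u = .lj_d2u(mix$eps, mix$sigma, r) + 2 * qq / r^3)
}

#' @export
pair_derivatives.periodic_pair_fluid <- function(potential, pair, r) {
  if (any(r <= 0)) stop("r must be positive")
  rc <- potential$cutoff
  u <- .lj_u(potential$eps, potential$sigma, r)
  du <- .lj_du(potential$eps, potential$sigma, r)
  d2u <- .lj_d2u(potential$eps, potential$sigma, r)
  urc <- .lj_u(potential$eps, potential$sigma, rc)
  durc <- .lj_du(potential$eps, potential$sigma, rc)
  inside <- r < rc
  list(u = ifelse(inside, u - urc - durc * (r - rc), 0),
       du = ifelse(inside, du - durc, 0),
       d2u = ifelse(inside, d2u, 0))
}

#' Convenience: classical forces at a configuration
#' @inheritParams evaluate
#' @export
classical_force <- function(potential, config) evaluate(potential, config)$forces

#' Finite-difference force check
#'
#' Central-difference gradient of the energy, for verifying that
#' analytic forces are the exact negative gradient.
#'
#' @inheritParams evaluate
#' @param h step, Angstrom.
#' @return N x 3 matrix of -dE/dx estimates.
#' @export
numeric_force <- function(potential, config, h = 1e-5) {
  F <- matrix(0, n_atoms(config), 3)
  for (a in seq_len(n_atoms(config))) for (k in 1:3) {
    cp <- config; cm <- config
    cp$positions[a, k] <- cp$positions[a, k] + h
    cm$positions[a, k] <- cm$positions[a, k] - h
    F[a, k] <- -(evaluate(potential, cp)$energy -
                 evaluate(potential, cm)$energy) / (2 * h)
  }
  F
}
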