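#' Flexible three-site toy water model
#'
#' A minimal flexible water model for exercising the full
#' sampling/learning pipeline on molecular clusters and small periodic
#' boxes: harmonic O-H bonds and H-O-H angle inside each molecule, plus
#' intermolecular Lennard-Jones on the oxygen sites and fixed point
#' charges on all sites.  Clusters use bare 1/r Coulomb; periodic boxes
#' use minimum-image shifted-force LJ and Coulomb within a cutoff, so
#' forces stay the exact negative energy gradient.
#'
#' Atoms are ordered O, H, H per molecule; molecules are identified by
#' that fixed three-atom schema (no bond perception).
#'
#' @param params parameter list as produced by [toywater3_params()].
#' @param cutoff intermolecular cutoff in Angstrom for periodic boxes
#'   (ignored for clusters); must be at most half the shortest box edge.
#' @return a \code{potential_surface} of kind \code{toywater3}.
#' @export
toywater3 <- function(params = toywater3_params(), cutoff = 4.5) {
  .new_potential("toywater3", list(params = params, cutoff = cutoff,
                                   cache = new.env(parent = emptyenv())))
}

#' Default toy-water parameters
#'
#' Values loosely modeled on simple flexible point-charge water models:
#' bond r0 0.9572 Angstrom with force constant 2200 kJ/mol/Angstrom^2,
#' angle 104.52 degrees with 320 kJ/mol/rad^2, oxygen LJ eps 0.65
#' kJ/mol and sigma 3.15 Angstrom, charges -0.84 e (O) and +0.42 e (H).
#'
#' @return named list of parameters.
#' @export
toywater3_params <- function() {
  list(r0 = 0.9572, kb = 2200, theta0 = 104.52 * pi / 180, ka = 320,
       eps = 0.65, sigma = 3.15, qO = -0.84, qH = 0.42)
}

.toywater_topology <- function(potential, elements) {
  n <- length(elements)
  key <- paste0("n", n)
  if (!is.null(potential$cache[[key]])) return(potential$cache[[key]])
  if (n %% 3 != 0) stop("toywater3 expects 3 atoms per molecule")
  nmol <- n / 3
  want <- rep(c("O", "H", "H"), nmol)
  if (!all(elements == want))
    stop("toywater3 expects atoms ordered O,H,H per molecule")
  o <- 3 * seq_len(nmol) - 2
  h1 <- o + 1; h2 <- o + 2
  mol_of <- rep(seq_len(nmol), each = 3)
  idx <- utils::combn(n, 2)
  inter <- mol_of[idx[1, ]] != mol_of[idx[2, ]]
  pi_ <- idx[1, inter]; pj <- idx[2, inter]
  topo <- list(nmol = nmol, o = o, h1 = h1, h2 = h2,
               pi = pi_, pj = pj,
               is_oo = elements[pi_] == "O" & elements[pj] == "O",
               qi_is_O = elements[pi_] == "O", qj_is_O = elements[pj] == "O")
  potential$cache[[key]] <- topo
  topo
}

#' @export
evaluate.toywater3 <- function(potential, config) {
  p <- potential$params
  topo <- .toywater_topology(potential, config$elements)
  pos <- config$positions
  F <- matrix(0, nrow(pos), 3)
  energy <- 0

  # bonds O-H1 and O-H2
  for (hcol in c("h1", "h2")) {
    h <- topo[[hcol]]
    u <- pos[h, , drop = FALSE] - pos[topo$o, , drop = FALSE]
    r <- sqrt(rowSums(u^2))
    energy <- energy + sum(0.5 * p$kb * (r - p$r0)^2)
    fh <- -p$kb * (r - p$r0) / r * u
    F[h, ] <- F[h, ] + fh
    F[topo$o, ] <- F[topo$o, ] - fh
  }

  # H-O-H angle
  u <- pos[topo$h1, , drop = FALSE] - pos[topo$o, , drop = FALSE]
  v <- pos[topo$h2, , drop = FALSE] - pos[topo$o, , drop = FALSE]
  ru <- sqrt(rowSums(u^2)); rv <- sqrt(rowSums(v^2))
  cth <- pmin(1, pmax(-1, rowSums(u * v) / (ru * rv)))
  th <- acos(cth)
  sth <- pmax(sqrt(1 - cth^2), 1e-12)
  energy <- energy + sum(0.5 * p$ka * (th - p$theta0)^2)
  dEdth <- p$ka * (th - p$theta0)
  dth_du <- (cth / ru^2 * u - v / (ru * rv)) / sth
  dth_dv <- (cth / rv^2 * v - u / (ru * rv)) / sth
  F[topo$h1, ] <- F[topo$h1, ] - dEdth * dth_du
  F[topo$h2, ] <- F[topo$h2, ] - dEdth * dth_dv
  F[topo$o, ] <- F[topo$o, ] + dEdth * (dth_du + dth_dv)

  # intermolecular LJ (O-O) + Coulomb (all site pairs)
  if (length(topo$pi)) {
    d <- pos[topo$pi, , drop = FALSE] - pos[topo$pj, , drop = FALSE]
    if (config$periodic) d <- min_image(d, config$cell)
    r <- sqrt(rowSums(d^2))
    qq <- .const$coulomb *
      ifelse(topo$qi_is_O, p$qO, p$qH) * ifelse(topo$qj_is_O, p$qO, p$qH)
    u_lj <- ifelse(topo$is_oo, .lj_u(p$eps, p$sigma, r), 0)
    du_lj <- ifelse(topo$is_oo, .lj_du(p$eps, p$sigma, r), 0)
    u_c <- qq / r
    du_c <- -qq / r^2
    if (config$periodic) {
      rc <- potential$cutoff
      if (rc > min(config$cell) / 2 + 1e-12)
        stop("cutoff exceeds half the shortest box edge")
      urc_lj <- ifelse(topo$is_oo, .lj_u(p$eps, p$sigma, rc), 0)
      durc_lj <- ifelse(topo$is_oo, .lj_du(p$eps, p$sigma, rc), 0)
      urc_c <- qq / rc
      durc_c <- -qq / rc^2
      inside <- r < rc
      upair <- ifelse(inside,
                      (u_lj - urc_lj - durc_lj * (r - rc)) +
                      (u_c - urc_c - durc_c * (r - rc)), 0)
      dupair <- ifelse(inside, (du_lj - durc_lj) + (du_c - durc_c), 0)
    } else {
      upair <- u_lj + u_c
      dupair <- du_lj + du_c
    }
    energy <- energy + sum(upair)
    fv <- -dupair / r * d
    acc_i <- rowsum(fv, topo$pi)
    F[as.integer(rownames(acc_i)), ] <- F[as.integer(rownames(acc_i)), ] + acc_i
    acc_j <- rowsum(fv, topo$pj)
    F[as.integer(rownames(acc_j)), ] <- F[as.integer(rownames(acc_j)), ] - acc_j
  }
  list(energy = energy, forces = F)
}
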