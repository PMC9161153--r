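#' Non-interacting (ideal-gas) potential
#'
#' Zero energy and forces for any configuration; useful as a reference
#' system for thermostat and pressure checks.
#' @export
ideal_gas <- function() .new_potential("ideal", list())

#' @export
evaluate.ideal <- function(potential, config)
  list(energy = 0, forces = matrix(0, n_atoms(config), 3), virial = 0)

#' Classical MD and machine-learned centroid MD
#'
#' Velocity-Verlet propagation with optional Langevin thermostat
#' (BAOAB splitting).  When a trained [train_correction()] model is
#' supplied, its predicted quantum force correction is added to the
#' classical force each step, which turns the run into
#' machine-learned centroid molecular dynamics (ML-CMD): classical
#' cost, centroid-level quantum statistics.  With \code{correction =
#' NULL} (or a zero-weight model) the run is plain classical MD, and
#' identical seeds give identical trajectories.
#'
#' @param potential the PES.
#' @param config initial [molecular_configuration()].
#' @param n_steps steps to integrate.
#' @param T temperature, K (sets Maxwell-Boltzmann start and the
#'   thermostat).
#' @param dt timestep, fs (default 0.5).
#' @param ensemble \code{"nvt"} (Langevin) or \code{"nve"}.
#' @param friction Langevin friction, 1/fs (default 1 ps^-1).
#' @param correction optional \code{correction_model}.
#' @param rng a [seeded_rng()], or \code{seed} an integer.
#' @param seed integer seed used if \code{rng} is missing.
#' @param stride collect a frame every \code{stride} steps.
#' @param velocities optional N x 3 initial velocities (Angstrom/fs);
#'   default Maxwell-Boltzmann.
#' @return an \code{md_trajectory}: \code{frames} (list of N x 3
#'   position matrices, unwrapped), \code{velocity_frames}, \code{log}
#'   (data frame: step, time_fs, T_inst, E_pot, E_tot, virial) and
#'   metadata.
#' @export
run_md <- function(potential, config, n_steps, T, dt = 0.5,
                   ensemble = c("nvt", "nve"), friction = 1e-3,
                   correction = NULL, rng = NULL, seed = 1, stride = 10,
                   velocities = NULL) {
  ensemble <- match.arg(ensemble)
  if (is.null(rng)) rng <- seeded_rng(seed)
  n <- n_atoms(config)
  m_int <- mass_to_energy_units(config$masses)
  kT <- .const$kB * T
  x <- config$positions
  v <- if (!is.null(velocities)) as.matrix(velocities)
       else matrix(rng_gauss(rng, n * 3), n, 3) * sqrt(kT / m_int)
  cfg <- config
  force_of <- function(x) {
    cfg$positions <- x
    ev <- evaluate(potential, cfg)
    if (!is.null(correction)) ev$forces <- ev$forces +
        predict(correction, cfg)
    ev
  }
  ev <- force_of(x)
  c1 <- exp(-friction * dt)
  c2 <- sqrt(kT / m_int * (1 - c1^2))
  frames <- list(); vframes <- list(); log <- list()
  for (step in seq_len(n_steps)) {
    v <- v + 0.5 * dt * ev$forces / m_int
    x <- x + 0.5 * dt * v
    if (ensemble == "nvt") {
      v <- v * c1 + c2 * matrix(rng_gauss(rng, n * 3), n, 3)
    }
    x <- x + 0.5 * dt * v
    ev <- force_of(x)
    v <- v + 0.5 * dt * ev$forces / m_int
    if (step %% stride == 0) {
      ke <- 0.5 * sum(m_int * v^2)
      frames[[length(frames) + 1L]] <- x
      vframes[[length(vframes) + 1L]] <- v
      log[[length(log) + 1L]] <-
        c(step = step, time_fs = step * dt,
          T_inst = 2 * ke / (3 * n * .const$kB),
          E_pot = ev$energy, E_tot = ev$energy + ke,
          virial = if (is.null(ev$virial)) NA_real_ else ev$virial)
    }
    if (!all(is.finite(x)))
      stop("force blow-up / non-finite positions at step ", step)
  }
  structure(list(frames = frames, velocity_frames = vframes,
                 log = as.data.frame(do.call(rbind, log)),
                 meta = list(dt = dt, stride = stride, T = T,
                             ensemble = ensemble, friction = friction,
                             elements = config$elements,
                             masses = config$masses, cell = config$cell,
                             periodic = config$periodic,
                             corrected = !is.null(correction))),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory: %d frames, %d atoms, %s, T=%g K%s>\n",
              length(x$frames), length(x$meta$elements),
              toupper(x$meta$ensemble), x$meta$T,
              if (x$meta$corrected) ", ML-CMD corrected" else ""))
  invisible(x)
}

#' Sampled 1D classical MD / ML-CMD (compiled fast path)
#'
#' Langevin dynamics of a 1D model system, optionally with a trained
#' coordinate-mode correction model added to the classical force,
#' returning positions sampled after burn-in.  Used for long
#' stationary-distribution runs where only the sampled coordinate is
#' needed.
#'
#' @param potential 1D \code{potential_surface}.
#' @param T temperature, K.
#' @param n_steps steps.
#' @param dt timestep, fs.
#' @param friction Langevin friction, 1/fs.
#' @param stride sample every so many steps.
#' @param burn_frac fraction discarded as burn-in.
#' @param seed integer seed.
#' @param correction optional coordinate-mode \code{correction_model}.
#' @param x0 initial position, Angstrom.
#' @return numeric vector of sampled positions.
#' @export
run_md_1d <- function(potential, T, n_steps, dt = 0.5, friction = 1e-3,
                      stride = 10, burn_frac = 0.1, seed = 1,
                      correction = NULL, x0 = 0) {
  stopifnot(is_1d_potential(potential))
  kind <- match(potential$kind,
                c("free1d", "harmonic1d", "quartic1d", "morse1d")) - 1L
  par <- switch(potential$kind, free1d = 0, harmonic1d = potential$k,
                quartic1d = potential$c,
                morse1d = c(potential$D, potential$a))
  m_int <- mass_to_energy_units(potential$mass)
  has_corr <- !is.null(correction)
  corr <- if (has_corr) .corr_as_md1d(correction) else list()
  md1d_run(kind, par, m_int, T, dt, friction, as.integer(n_steps),
           as.integer(stride), burn_frac, as.integer(seed), x0,
           has_corr, corr)
}

#' Virial pressure trace of a periodic trajectory
#'
#' Pair-virial pressure per collected frame:
#' P = (N kB T_inst + W/3) / V, with W the pair virial
#' sum r_ij . f_ij, converted to bar.
#'
#' @param traj an \code{md_trajectory} of a periodic system.
#' @param potential the PES (used to recompute the virial when the
#'   trajectory log lacks it).
#' @return numeric vector of pressures (bar), one per frame.
#' @export
virial_pressure <- function(traj, potential) {
  if (!traj$meta$periodic)
    stop("virial pressure needs a periodic trajectory")
  V <- prod(traj$meta$cell)
  n <- length(traj$meta$elements)
  W <- traj$log$virial
  if (anyNA(W)) {
    W <- vapply(traj$frames, function(x) {
      cfg <- molecular_configuration(traj$meta$elements, x,
                                     masses = traj$meta$masses,
                                     cell = traj$meta$cell)
      ev <- evaluate(potential, cfg)
      if (is.null(ev$virial)) stop("potential reports no pair virial")
      ev$virial
    }, 0)
  }
  (n * .const$kB * traj$log$T_inst + W / 3) / V * .const$pressure_bar
}
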