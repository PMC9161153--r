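#' Ring-polymer state
#'
#' The discrete imaginary-time path: P replicas (beads) of an N-atom
#' configuration with conjugate momenta.  The ring polymer is sampled
#' at the physical temperature with inter-bead spring frequency
#' omega_P = sqrt(P)/(beta hbar) and the physical potential entering as
#' U/P per bead; its equilibrium bead distribution converges to the
#' quantum Boltzmann distribution as P grows.
#'
#' @param config a [molecular_configuration()]; beads start collapsed
#'   onto it.
#' @param P bead count (P = 1 is classical mechanics).
#' @param T temperature, K.
#' @param rng optional [seeded_rng()]; if given, momenta are drawn from
#'   the Maxwell-Boltzmann distribution, otherwise they start at zero.
#' @return object of class \code{ring_polymer_state}.
#' @export
ring_polymer_state <- function(config, P, T, rng = NULL) {
  stopifnot(P >= 1)
  n <- n_atoms(config)
  beads <- array(rep(config$positions, each = P), dim = c(P, n, 3))
  m_int <- mass_to_energy_units(config$masses)
  momenta <- array(0, dim = c(P, n, 3))
  if (!is.null(rng)) {
    sd <- sqrt(m_int * .const$kB * T)
    momenta <- array(rng_gauss(rng, P * n * 3), dim = c(P, n, 3)) *
      rep(rep(sd, each = P), times = 3)
  }
  structure(list(beads = beads, momenta = momenta, P = P, T = T,
                 beta = beta_of(T), elements = config$elements,
                 masses = config$masses, m_int = m_int,
                 cell = config$cell, periodic = config$periodic),
            class = "ring_polymer_state")
}

#' @export
print.ring_polymer_state <- function(x, ...) {
  cat(sprintf("<ring_polymer_state: P=%d beads, %d atoms, T=%g K>\n",
              x$P, dim(x$beads)[2], x$T))
  invisible(x)
}

#' Centroid of a ring-polymer state
#'
#' Per-atom arithmetic mean over beads.  For periodic systems the mean
#' is taken over the unwrapped bead images nearest the first bead, so a
#' polymer straddling the box boundary gets a physical centroid.
#'
#' @param state a [ring_polymer_state()].
#' @return a [molecular_configuration()].
#' @export
centroid <- function(state) {
  stopifnot(inherits(state, "ring_polymer_state"))
  P <- state$P
  if (state$periodic && P > 1) {
    ref <- state$beads[1, , , drop = TRUE]
    if (is.null(dim(ref))) ref <- matrix(ref, ncol = 3)
    acc <- matrix(0, dim(state$beads)[2], 3)
    for (k in seq_len(P)) {
      bk <- matrix(state$beads[k, , ], ncol = 3)
      acc <- acc + ref + min_image(bk - ref, state$cell)
    }
    pos <- acc / P
  } else {
    pos <- apply(state$beads, c(2, 3), mean)
    if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  }
  molecular_configuration(state$elements, pos, masses = state$masses,
                          cell = state$cell)
}

#' Inter-bead spring energy
#'
#' Sum over beads, atoms and Cartesian components of
#' m omega_P^2 |x_{k+1} - x_k|^2 / 2 with cyclic closure and
#' omega_P = sqrt(P)/(beta hbar).  Zero by definition for P = 1.
#'
#' @param state a [ring_polymer_state()].
#' @return energy in kJ/mol.
#' @export
spring_energy <- function(state) {
  P <- state$P
  if (P == 1) return(0)
  wP <- sqrt(P) / (state$beta * .const$hbar)
  nxt <- c(2:P, 1)
  d <- state$beads[nxt, , , drop = FALSE] - state$beads
  m3 <- rep(rep(state$m_int, each = P), times = 3)
  sum(0.5 * m3 * wP^2 * d^2)
}

#' Normal-mode transform of the cyclic ring polymer
#'
#' Orthonormal real transform diagonalizing the cyclic spring matrix.
#' Mode 0 is the centroid scaled by sqrt(P) (so mode-0 coordinate /
#' sqrt(P) equals the centroid); modes k and P-k share the free
#' ring-polymer frequency 2 omega_P sin(k pi / P).
#'
#' @param P bead count.
#' @return P x P orthogonal matrix C with bead coordinates x = C q.
#' @export
normal_mode_matrix <- function(P) {
  C <- matrix(0, P, P)
  j <- 0:(P - 1)
  for (k in 0:(P - 1)) {
    C[, k + 1] <-
      if (k == 0) sqrt(1 / P)
      else if (2 * k == P) sqrt(1 / P) * (-1)^j
      else if (2 * k < P) sqrt(2 / P) * cos(2 * pi * j * k / P)
      else sqrt(2 / P) * sin(2 * pi * j * (P - k) / P)
  }
  C
}

#' @rdname normal_mode_matrix
#' @param x P x d matrix of bead coordinates (columns are degrees of
#'   freedom), or a \code{ring_polymer_state} bead array reshaped by the
#'   caller.
#' @param inverse if TRUE, map mode coordinates back to beads.
#' @export
normal_mode_transform <- function(x, inverse = FALSE) {
  x <- as.matrix(x)
  C <- normal_mode_matrix(nrow(x))
  if (inverse) C %*% x else crossprod(C, x)
}

#' @rdname normal_mode_matrix
#' @param T temperature, K (sets omega_P).
#' @return \code{free_rp_frequencies}: the P free ring-polymer mode
#'   frequencies 2 omega_P sin(k pi/P), rad/fs, in transform order.
#' @export
free_rp_frequencies <- function(P, T) {
  wP <- sqrt(P) / (beta_of(T) * .const$hbar)
  2 * wP * sin(pi * (0:(P - 1)) / P)
}

# ---------------------------------------------------------------------------
# Thermostatted PIMD propagation (normal modes, BAOAB, PILE friction)
# ---------------------------------------------------------------------------

#' Run thermostatted PIMD
#'
#' Propagates a ring polymer with exact free-ring-polymer normal-mode
#' evolution, velocity-Verlet force splitting and per-mode Langevin
#' (PILE) friction: the centroid mode gets \code{friction}, internal
#' modes are critically damped at twice their frequency.  With
#' \code{fixed_centroid = TRUE} the centroid mode is frozen (momentum
#' zeroed every stage), realising fixed-centroid sampling.
#'
#' @param state a [ring_polymer_state()].
#' @param potential the PES.
#' @param n_steps number of steps.
#' @param dt timestep, fs (default 0.5).
#' @param friction centroid Langevin friction, 1/fs (default 1 ps^-1 =
#'   0.001/fs); 0 disables the thermostat entirely.
#' @param fixed_centroid freeze the centroid mode.
#' @param rng a [seeded_rng()] (required when thermostatted).
#' @param stride collect observables every \code{stride} steps.
#' @param keep_beads store bead frames (memory-heavy; needed for
#'   [bead_width()]).
#' @return a \code{pimd_trajectory}: list with \code{centroid_frames},
#'   optional \code{bead_frames}, \code{energies} (total ring-polymer
#'   Hamiltonian), \code{mean_forces} (per-frame bead-averaged physical
#'   force), \code{state} (final), and metadata.
#' @export
pimd_run <- function(state, potential, n_steps, dt = 0.5, friction = 1e-3,
                     fixed_centroid = FALSE, rng = NULL, stride = 10,
                     keep_beads = FALSE) {
  P <- state$P; n <- dim(state$beads)[2]; d <- 3L * n
  if (friction > 0 && is.null(rng)) stop("thermostatted run needs an rng")
  C <- normal_mode_matrix(P)
  wk <- free_rp_frequencies(P, state$T)
  m3 <- rep(state$m_int, times = 3)          # length 3N, column masses
  kT <- .const$kB * state$T
  X <- matrix(state$beads, P, d)             # beads as P x 3N
  Pm <- matrix(state$momenta, P, d)
  Q <- crossprod(C, X)
  Pq <- crossprod(C, Pm)
  if (fixed_centroid) Pq[1, ] <- 0

  g <- c(friction, 2 * wk[-1])
  c1 <- exp(-g * dt)
  c2m <- sqrt(outer(1 - c1^2, m3 * kT))      # P x 3N noise amplitudes
  cwt <- cos(wk * dt / 2); swt <- sin(wk * dt / 2)

  bead_forces <- function(Q) {
    X <- C %*% Q
    ev <- evaluate_beads(potential, state$elements, state$masses,
                         array(X, c(P, n, 3)), state$cell)
    list(F = matrix(ev$F, P, d), E = ev$E, X = X)
  }

  bf <- bead_forces(Q)
  Fq <- crossprod(C, bf$F) / P
  frames <- list(); beads_out <- list(); energies <- c(); mean_forces <- list()
  collect <- function(bf, Q, Pq) {
    xc <- matrix(Q[1, ] / sqrt(P), n, 3)
    e_tot <- sum(Pq^2 / (2 * rep(m3, each = P))) +
      sum(0.5 * rep(m3, each = P) * wk^2 * Q^2) + bf$E / P
    fbar <- matrix(colMeans(bf$F), n, 3)
    list(xc = xc, e = e_tot, fbar = fbar)
  }

  mw <- if (P > 1) outer(wk[2:P], m3) else NULL
  a_half <- function() {
    if (!fixed_centroid) Q[1, ] <<- Q[1, ] + 0.5 * dt * Pq[1, ] / m3
    if (P > 1) {
      ks <- 2:P
      Qk <- Q[ks, , drop = FALSE]; Pk <- Pq[ks, , drop = FALSE]
      Qn <- Qk * cwt[ks] + Pk / mw * swt[ks]
      Pq[ks, ] <<- Pk * cwt[ks] - mw * Qk * swt[ks]
      Q[ks, ] <<- Qn
    }
  }

  for (step in seq_len(n_steps)) {
    Pq <- Pq + 0.5 * dt * Fq
    if (fixed_centroid) Pq[1, ] <- 0
    a_half()
    if (friction > 0) {
      Z <- matrix(rng_gauss(rng, P * d), P, d)
      Pq <- Pq * c1 + c2m * Z
      if (fixed_centroid) Pq[1, ] <- 0
    }
    a_half()
    bf <- bead_forces(Q)
    Fq <- crossprod(C, bf$F) / P
    Pq <- Pq + 0.5 * dt * Fq
    if (fixed_centroid) Pq[1, ] <- 0

    if (step %% stride == 0) {
      obs <- collect(bf, Q, Pq)
      frames[[length(frames) + 1L]] <- obs$xc
      energies <- c(energies, obs$e)
      mean_forces[[length(mean_forces) + 1L]] <- obs$fbar
      if (keep_beads) beads_out[[length(beads_out) + 1L]] <-
          array(bf$X, dim = c(P, n, 3))
    }
  }

  state$beads <- array(C %*% Q, dim = c(P, n, 3))
  state$momenta <- array(C %*% Pq, dim = c(P, n, 3))
  structure(list(centroid_frames = frames, bead_frames = beads_out,
                 energies = energies, mean_forces = mean_forces,
                 state = state,
                 meta = list(n_steps = n_steps, dt = dt, stride = stride,
                             friction = friction, T = state$T, P = P,
                             fixed_centroid = fixed_centroid)),
            class = "pimd_trajectory")
}

#' Bead-distribution second moment
#'
#' Time-and-bead average of the squared bead displacement from the
#' centroid, per atom and Cartesian component.
#'
#' @param traj a \code{pimd_trajectory} run with \code{keep_beads =
#'   TRUE}.
#' @param atoms optional integer selection of atoms.
#' @return N_sel x 3 matrix of second moments (Angstrom^2).
#' @export
bead_width <- function(traj, atoms = NULL) {
  if (!length(traj$bead_frames))
    stop("trajectory carries no bead frames (keep_beads = FALSE?)")
  n <- dim(traj$bead_frames[[1]])[2]
  if (is.null(atoms)) atoms <- seq_len(n)
  if (!length(atoms)) stop("empty atom selection")
  acc <- matrix(0, length(atoms), 3)
  for (fr in traj$bead_frames) {
    xc <- apply(fr, c(2, 3), mean)
    for (ia in seq_along(atoms)) {
      a <- atoms[ia]
      dxa <- sweep(fr[, a, , drop = TRUE], 2, xc[a, ])
      if (is.null(dim(dxa))) dxa <- matrix(dxa, ncol = 3)
      acc[ia, ] <- acc[ia, ] + colMeans(dxa^2)
    }
  }
  acc / length(traj$bead_frames)
}

#' Fixed-centroid sampling of the quantum centroid force
#'
#' Runs fixed-centroid PIMD at a given centroid geometry and returns
#' the converged bead-averaged physical force with its block-averaged
#' standard error, alongside the classical force at the centroid: their
#' difference is the quantum centroid force correction, the learning
#' target.  One-dimensional model potentials use a compiled sampler;
#' molecular systems use the R normal-mode propagator.
#'
#' @param centroid_geom the centroid [molecular_configuration()].
#' @param potential the PES.
#' @param T temperature, K.
#' @param P bead count; default policy is 32 beads at T >= 200 K and 64
#'   below.
#' @param n_steps sampling steps.
#' @param dt timestep, fs.
#' @param friction centroid Langevin friction, 1/fs.
#' @param seed integer seed (or an [seeded_rng()] via \code{rng}).
#' @param burn_frac fraction of steps discarded as burn-in.
#' @param n_blocks blocks for the standard-error estimate.
#' @param tolerance convergence tolerance on the force SEM,
#'   kJ/(mol Angstrom); a record whose max SEM exceeds it is flagged
#'   (with a warning), not dropped.
#' @return a \code{centroid_force_record}.
#' @export
sample_fixed_centroid <- function(centroid_geom, potential, T, P = NULL,
                                  n_steps = 20000, dt = 0.5,
                                  friction = 1e-3, seed = 1,
                                  burn_frac = 0.1, n_blocks = 20,
                                  tolerance = 0.2) {
  if (is.null(P)) P <- if (T >= 200) 32L else 64L
  meta <- list(T = T, P = P, n_steps = n_steps, dt = dt,
               friction = friction, seed = seed)
  cls <- classical_force(potential, centroid_geom)
  if (is_1d_potential(potential)) {
    kind <- match(potential$kind, c("free1d", "harmonic1d", "quartic1d",
                                    "morse1d")) - 1L
    par <- switch(potential$kind, free1d = 0,
                  harmonic1d = potential$k, quartic1d = potential$c,
                  morse1d = c(potential$D, potential$a))
    m_int <- mass_to_energy_units(centroid_geom$masses[1])
    out <- rp1d_sample(kind, par, m_int, T, P, n_steps, dt, friction,
                       centroid_geom$positions[1, 1], TRUE,
                       as.integer(seed), burn_frac, n_blocks, 0L, TRUE)
    mean_force <- matrix(0, 1, 3); mean_force[1, 1] <- out$mean_force
    sem <- matrix(0, 1, 3); sem[1, 1] <- out$force_sem
    meta$width <- out$width
  } else {
    rng <- if (inherits(seed, "mlcmd_rng")) seed else seeded_rng(seed)
    st <- ring_polymer_state(centroid_geom, P, T, rng = rng)
    traj <- pimd_run(st, potential, n_steps, dt = dt, friction = friction,
                     fixed_centroid = TRUE, rng = rng, stride = 1,
                     keep_beads = FALSE)
    n_burn <- floor(burn_frac * n_steps)
    use <- traj$mean_forces[(n_burn + 1):length(traj$mean_forces)]
    arr <- simplify2array(use)                       # N x 3 x steps
    mean_force <- apply(arr, c(1, 2), mean)
    nb <- n_blocks
    bl <- floor(dim(arr)[3] / nb)
    bm <- vapply(seq_len(nb), function(b)
      apply(arr[, , ((b - 1) * bl + 1):(b * bl), drop = FALSE], c(1, 2), mean),
      matrix(0, nrow(mean_force), 3))
    sem <- apply(bm, c(1, 2), stats::sd) / sqrt(nb)
  }
  converged <- max(sem) <= tolerance
  if (!converged)
    warning(sprintf("centroid force not converged: max SEM %.3g > %.3g",
                    max(sem), tolerance))
  structure(list(geometry = centroid_geom, mean_force = mean_force,
                 force_sem = sem, classical_force = cls,
                 delta_force = mean_force - cls, converged = converged,
                 meta = meta),
            class = "centroid_force_record")
}

#' @export
print.centroid_force_record <- function(x, ...) {
  cat(sprintf(paste0("<centroid_force_record: %d atoms, T=%g K, P=%d, ",
                     "max |dF|=%.3g, max SEM=%.3g kJ/mol/A%s>\n"),
              nrow(x$mean_force), x$meta$T, x$meta$P,
              max(abs(x$delta_force)), max(x$force_sem),
              if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}

#' Dump a ring-polymer trajectory as extended XYZ
#'
#' Writes the stored bead frames as a multi-frame extended-XYZ file,
#' one frame per (time frame, bead) with \code{frame} and \code{bead}
#' keys on the comment line.
#'
#' @param traj a \code{pimd_trajectory} run with \code{keep_beads =
#'   TRUE}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_rp_xyz <- function(traj, path) {
  if (!length(traj$bead_frames))
    stop("trajectory carries no bead frames (keep_beads = FALSE?)")
  st <- traj$state
  configs <- list(); fields <- list()
  for (f in seq_along(traj$bead_frames)) {
    arr <- traj$bead_frames[[f]]
    for (k in seq_len(dim(arr)[1])) {
      configs[[length(configs) + 1L]] <-
        molecular_configuration(st$elements, matrix(arr[k, , ], ncol = 3),
                                masses = st$masses, cell = st$cell)
      fields[[length(fields) + 1L]] <- list(frame = f, bead = k)
    }
  }
  write_xyz(configs, path, comment_fields = fields)
}
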