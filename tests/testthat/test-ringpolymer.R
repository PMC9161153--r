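test_that("centroid is the bead mean, with periodic unwrapping", {
  cfg <- toy_cluster()
  st <- ring_polymer_state(cfg, 4, 300)
  # collapsed beads: centroid is the starting configuration
  expect_equal(centroid(st)$positions, cfg$positions, tolerance = 1e-14)
  # symmetric 1D displacement averages to zero
  st$beads[1, 1, 1] <- st$beads[1, 1, 1] + 0.3
  st$beads[2, 1, 1] <- st$beads[2, 1, 1] - 0.3
  expect_equal(centroid(st)$positions[1, 1], cfg$positions[1, 1],
               tolerance = 1e-14)
  # random state: equals the brute-force mean over beads
  rng <- seeded_rng(5)
  st32 <- ring_polymer_state(cfg, 32, 300)
  st32$beads <- st32$beads + array(rng_gauss(rng, 32 * 4 * 3) * 0.1,
                                   c(32, 4, 3))
  expect_equal(centroid(st32)$positions, apply(st32$beads, c(2, 3), mean),
               tolerance = 1e-12)
  # periodic: a polymer straddling the boundary unwraps to a sane mean
  box <- molecular_configuration("X", matrix(c(0.05, 5, 5), 1),
                                 masses = 1, cell = c(10, 10, 10))
  stp <- ring_polymer_state(box, 2, 300)
  stp$beads[2, 1, 1] <- 9.95    # same physical point, 0.1 apart via image
  expect_equal(centroid(stp)$positions[1, 1], 0, tolerance = 1e-12)
})

test_that("spring energy follows the cyclic spring formula", {
  cfg <- config_1d(0)
  st <- ring_polymer_state(cfg, 2, 300)
  expect_equal(spring_energy(st), 0)
  # two beads separated by d: two springs of m wP^2 d^2 / 2 each
  d <- 0.21
  st$beads[1, 1, 1] <- d / 2; st$beads[2, 1, 1] <- -d / 2
  wP <- sqrt(2) / (mlcmd:::beta_of(300) * const$hbar)
  expect_equal(spring_energy(st),
               mass_to_energy_units(1.008) * wP^2 * d^2, tolerance = 1e-12)
  # invariant under cyclic relabeling
  st8 <- ring_polymer_state(toy_cluster(), 8, 200)
  st8$beads <- st8$beads + array(rng_gauss(seeded_rng(2), 8 * 4 * 3) * 0.1,
                                 c(8, 4, 3))
  e1 <- spring_energy(st8)
  st8$beads <- st8$beads[c(3:8, 1:2), , , drop = FALSE]
  expect_equal(spring_energy(st8), e1, tolerance = 1e-12)
  # P = 1 has no springs
  expect_equal(spring_energy(ring_polymer_state(cfg, 1, 300)), 0)
})

test_that("normal-mode transform is orthogonal and diagonalizes the springs", {
  for (P in c(2, 7, 16)) {
    C <- normal_mode_matrix(P)
    expect_equal(crossprod(C), diag(P), tolerance = 1e-12)
    # eigenvalues of the cyclic spring matrix are the mode frequencies
    K <- matrix(0, P, P)
    for (j in seq_len(P)) {        # spring between bead j and j+1 (cyclic)
      nx <- j %% P + 1
      K[j, j] <- K[j, j] + 1; K[nx, nx] <- K[nx, nx] + 1
      K[j, nx] <- K[j, nx] - 1; K[nx, j] <- K[nx, j] - 1
    }
    lam <- diag(crossprod(C, K %*% C))      # in units of omega_P^2
    expect_equal(sort(lam), sort((2 * sin(pi * (0:(P - 1)) / P))^2),
                 tolerance = 1e-10)
  }
  # round-trip identity and mode-0 = sqrt(P) * centroid
  x <- matrix(rng_gauss(seeded_rng(3), 16 * 5), 16, 5)
  q <- normal_mode_transform(x)
  expect_equal(normal_mode_transform(q, inverse = TRUE), x,
               tolerance = 1e-12)
  expect_equal(q[1, ], sqrt(16) * colMeans(x), tolerance = 1e-12)
  # free_rp_frequencies matches 2 omega_P sin(k pi / P)
  wk <- free_rp_frequencies(8, 300)
  wP <- sqrt(8) / (mlcmd:::beta_of(300) * const$hbar)
  expect_equal(wk, 2 * wP * sin(pi * (0:7) / 8), tolerance = 1e-12)
})

test_that("fixed-centroid propagation freezes the centroid exactly", {
  cfg <- octamer_fixture()[[1]]
  st <- ring_polymer_state(cfg, 8, 300, rng = seeded_rng(6))
  traj <- pimd_run(st, toywater3(), n_steps = 200, fixed_centroid = TRUE,
                   rng = seeded_rng(7), stride = 50)
  for (fr in traj$centroid_frames)
    expect_lt(max(abs(fr - cfg$positions)), 1e-8)
})

test_that("free-particle fixed-centroid widths match the finite-P formula", {
  m <- mass_to_energy_units(1.008)
  out <- mlcmd:::rp1d_sample(0L, 0, m, 300, 32L, 150000L, 0.5, 1e-3, 0.5,
                             TRUE, 42L, 0.1, 20L, 0L, TRUE)
  w_exp <- fhc_width(300, 1.008) * (1 - 1 / 32^2)
  expect_lt(abs(out$width - w_exp), 3.5 * out$width_sem)
  expect_equal(out$mean_force, 0, tolerance = 1e-12)
})

test_that("harmonic centroid force equals the classical force", {
  # the centroid PMF of a harmonic oscillator is the potential itself
  pot <- harmonic1d(omega_cm1 = 670, mass = 1.008)
  rec <- sample_fixed_centroid(config_1d(0.5), pot, T = 300, P = 32,
                               n_steps = 50000, seed = 11)
  expect_lt(abs(rec$delta_force[1, 1]), 3 * max(rec$force_sem[1, 1], 1e-10))
  expect_true(rec$converged)
})

test_that("ring-polymer Hamiltonian is conserved without a thermostat", {
  m <- mass_to_energy_units(1.008)
  k <- m * cm1_to_angular(670)^2
  out <- mlcmd:::rp1d_sample(1L, k, m, 300, 16L, 10000L, 0.25, 0, 0.3,
                             FALSE, 5L, 0, 1L, 10L, FALSE)
  e <- out$energies
  expect_lt(max(abs(e - e[1])) / abs(e[1]), 1e-4)
})

test_that("virial kinetic-energy estimator matches the QHO closed form", {
  m <- mass_to_energy_units(1.008)
  om <- cm1_to_angular(670)
  T <- 300; P <- 64L
  out <- mlcmd:::rp1d_sample(1L, m * om^2, m, T, P, 400000L, 0.25, 1e-3,
                             0, FALSE, 99L, 0.1, 20L, 0L, TRUE)
  # centroid-virial estimator: kT/2 - <(x - x_c) . F> / 2
  ke <- const$kB * T / 2 - out$mean_virial / 2
  hw <- const$hbar * om
  beta <- mlcmd:::beta_of(T)
  ke_exact <- (hw / 4) / tanh(beta * hw / 2)
  expect_lt(abs(ke - ke_exact) / ke_exact, 0.02)
})

test_that("P = 1 ring-polymer dynamics is classical MD with the same seed", {
  m <- mass_to_energy_units(1.008)
  out <- mlcmd:::rp1d_sample(2L, 10, m, 300, 1L, 5000L, 0.5, 1e-3, 0.4,
                             FALSE, 77L, 0.1, 5L, 10L, TRUE)
  xs <- mlcmd:::md1d_run(2L, 10, m, 300, 0.5, 1e-3, 5000L, 10L, 0.1, 77L,
                         0.4, FALSE, list())
  n <- min(length(out$xc), length(xs))
  expect_equal(out$xc[seq_len(n)], xs[seq_len(n)], tolerance = 1e-12)
})

test_that("fixed-centroid sampling warns when unconverged and stores SEMs", {
  cfg <- octamer_fixture()[[1]]
  expect_warning(
    rec <- sample_fixed_centroid(cfg, toywater3(), T = 300, P = 4,
                                 n_steps = 300, seed = 3, tolerance = 0.01),
    "not converged")
  expect_false(rec$converged)
  expect_true(all(rec$force_sem > 0))
  expect_true(all(is.finite(rec$delta_force)))
})
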