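test_that("NVE velocity-Verlet conserves energy on the harmonic oscillator", {
  # shadow-Hamiltonian energy oscillation scales as (omega dt)^2 / 8;
  # at omega dt ~ 0.02 that sits below 1e-4 relative, with no drift
  pot <- harmonic1d(omega_cm1 = 200, mass = 1.008)
  traj <- run_md(pot, config_1d(0.3), n_steps = 20000, T = 300,
                 ensemble = "nve", dt = 0.5, seed = 4, stride = 50)
  e <- traj$log$E_tot
  expect_lt(max(abs(e - e[1])) / abs(e[1]), 1e-4)
  # quadratic shrinkage with dt (order-2 integrator)
  pot2 <- harmonic1d(omega_cm1 = 670, mass = 1.008)
  dev <- vapply(c(0.5, 0.25), function(dt) {
    tr <- run_md(pot2, config_1d(0.3), n_steps = round(5000 / dt), T = 300,
                 ensemble = "nve", dt = dt, seed = 4, stride = 50)
    max(abs(tr$log$E_tot - tr$log$E_tot[1])) / abs(tr$log$E_tot[1])
  }, 0)
  expect_gt(dev[1] / dev[2], 2.5)
})

test_that("a zero-weight correction reproduces classical MD exactly", {
  pot <- quartic1d(c = 10)
  dp <- descriptor_params_1d(-2, 2, 7)
  zero <- random_correction_model(dp, hidden = c(4, 4), seed = 1)
  for (e in seq_along(zero$nets)) zero$nets[[e]]$w3[] <- 0
  t1 <- run_md(pot, config_1d(0.5), n_steps = 2000, T = 300, seed = 9,
               stride = 20)
  t2 <- run_md(pot, config_1d(0.5), n_steps = 2000, T = 300, seed = 9,
               stride = 20, correction = zero)
  expect_lt(max(abs(t1$frames[[100]] - t2$frames[[100]])), 1e-10)
  # compiled 1D path agrees too
  s1 <- run_md_1d(pot, T = 300, n_steps = 2000, seed = 9, x0 = 0.5)
  s2 <- run_md_1d(pot, T = 300, n_steps = 2000, seed = 9, x0 = 0.5,
                  correction = zero)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("Langevin free-particle diffusion follows kT/(m gamma)", {
  # D averaged over independent trajectories (a single-particle MSD
  # estimate carries ~10% noise at this length; the mean is unbiased)
  m_amu <- 1.008; gamma <- 0.01; T <- 250
  D_exp <- const$kB * T / (mass_to_energy_units(m_amu) * gamma) * 1000
  Ds <- vapply(1:12, function(seed) {
    xs <- run_md_1d(free1d(mass = m_amu), T = T, n_steps = 2e6, dt = 0.5,
                    friction = gamma, stride = 40, seed = seed)
    fake <- structure(list(
      frames = lapply(xs, function(x) matrix(c(x, 0, 0), 1)),
      meta = list(dt = 0.5, stride = 40, elements = "H", masses = m_amu,
                  cell = NULL, periodic = FALSE)), class = "md_trajectory")
    msd_diffusion(fake, dims = 1, fit_window = c(600, 4000),
                  max_lag = 300)$D
  }, 0)
  expect_lt(abs(mean(Ds) - D_exp) / D_exp, 0.05)
})

test_that("virial pressure recovers the ideal gas and the pair formula", {
  # non-interacting particles: P V = N k T within a few SE
  box <- make_fixtures("ljfluid_32", seed = 3)
  traj <- run_md(ideal_gas(), box, n_steps = 10000, T = 120, seed = 5,
                 friction = 0.01, stride = 20)
  p <- virial_pressure(traj, ideal_gas())
  p_id <- 32 * const$kB * 120 / prod(box$cell) * const$pressure_bar
  # velocity decorrelation time 1/gamma = 100 fs = 5 frames
  se <- sd(p) / sqrt(length(p) / 10)
  expect_lt(abs(mean(p) - p_id), 4 * se)
  # two fixed particles: virial term equals -r u'(r) exactly
  fluid <- periodic_pair_fluid(eps = 1, sigma = 2.8, cutoff = 6)
  two <- molecular_configuration(rep("X", 2),
                                 rbind(c(0, 0, 0), c(3.2, 0, 0)),
                                 masses = rep(2.016, 2),
                                 cell = c(14, 14, 14))
  ev <- evaluate(fluid, two)
  pd <- pair_derivatives(fluid, c("X", "X"), 3.2)
  expect_equal(ev$virial, -3.2 * pd$du, tolerance = 1e-10)
  expect_error(virial_pressure(
    run_md(quartic1d(), config_1d(0), n_steps = 50, T = 300, seed = 1),
    quartic1d()), "periodic")
})

test_that("LJ fluid pressure approaches the second-virial estimate when dilute", {
  eps <- 0.4; sigma <- 2.8; T <- 150
  fluid <- periodic_pair_fluid(eps = eps, sigma = sigma, cutoff = 8)
  # a dilute box: 32 atoms at low density
  rng <- seeded_rng(8)
  L <- 40
  pos <- matrix(rng_unif(rng, 96) * L, 32, 3)
  cfg <- molecular_configuration(rep("X", 32), pos, masses = c(X = 20),
                                 cell = rep(L, 3))
  traj <- run_md(fluid, cfg, n_steps = 12000, T = T, seed = 31, stride = 20,
                 dt = 2)
  p <- mean(virial_pressure(traj, fluid))
  # B2 from quadrature of the shifted-force pair potential
  r <- seq(1e-3, 8, length.out = 4000)
  u <- pair_derivatives(fluid, c("X", "X"), r)$u
  beta <- mlcmd:::beta_of(T)
  B2 <- -2 * pi * sum((exp(-beta * u) - 1) * r^2) * (r[2] - r[1])
  rho <- 32 / L^3
  p_b2 <- (rho * const$kB * T * (1 + B2 * rho)) * const$pressure_bar
  expect_lt(abs(p - p_b2) / abs(p_b2), 0.1)
})

test_that("ML-CMD restores the quantum centroid RDF of a cold LJ fluid", {
  # end-to-end: PIMD centroid reference -> fixed-centroid labels ->
  # trained correction -> ML-CMD at classical cost; the centroid RDF
  # from ML-CMD must beat classical MD in L1 distance to the reference
  fluid <- periodic_pair_fluid(eps = 1, sigma = 2.8, cutoff = 6.5,
                               element = "X", mass = 2.016)
  box <- make_fixtures("ljfluid_32", seed = 31)
  TK <- 30
  eq <- run_md(fluid, box, n_steps = 3000, T = TK, dt = 1, seed = 32,
               stride = 3000)
  cfg0 <- box; cfg0$positions <- eq$frames[[1]]
  st <- ring_polymer_state(cfg0, 16, TK, rng = seeded_rng(33))
  ref <- pimd_run(st, fluid, n_steps = 5000, dt = 1, friction = 1e-3,
                  rng = seeded_rng(34), stride = 10)
  g_ref <- rdf(ref, c("X", "X"), r_max = 6.5, n_bins = 40)
  cls <- run_md(fluid, cfg0, n_steps = 5000, T = TK, dt = 1, seed = 35,
                stride = 10)
  g_cls <- rdf(cls, c("X", "X"), r_max = 6.5, n_bins = 40)
  train_cfgs <- lapply(seq(20, 460, by = 40), function(i) {
    cc <- cfg0; cc$positions <- ref$centroid_frames[[i]]; cc
  })
  ts <- suppressWarnings(
    build_training_set(train_cfgs, fluid, T = TK, P = 16, n_steps = 2500,
                       dt = 1, tolerance = 1, seed = 36))
  mod <- suppressWarnings(
    train_correction(ts, descriptor_params(cutoff = 4, elements = "X"),
                     hidden = c(8, 8), seed = 37, lm_maxit = 40,
                     loss_tol = 1))
  mlc <- run_md(fluid, cfg0, n_steps = 5000, T = TK, dt = 1, seed = 38,
                stride = 10, correction = mod)
  g_ml <- rdf(mlc, c("X", "X"), r_max = 6.5, n_bins = 40)
  l1_cls <- sum(abs(g_cls$g - g_ref$g))
  l1_ml <- sum(abs(g_ml$g - g_ref$g))
  expect_lt(l1_ml, l1_cls)
  expect_lt(l1_ml, 0.5 * l1_cls)   # not marginal: a clear improvement
})
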