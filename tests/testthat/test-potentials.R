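test_that("1D model potentials match their closed forms", {
  pot <- harmonic1d(k = 2)
  ev <- evaluate(pot, config_1d(2))
  expect_equal(ev$energy, 4)
  expect_equal(ev$forces[1, 1], -4)
  expect_equal(evaluate(quartic1d(c = 8), config_1d(0.5))$energy,
               0.25 * 8 * 0.5^4)
  # harmonic1d from a wavenumber: k = m omega^2
  potw <- harmonic1d(omega_cm1 = 670, mass = 1.008)
  expect_equal(potw$k, mass_to_energy_units(1.008) * cm1_to_angular(670)^2)
})

test_that("LJ landmarks and analytic pair derivatives", {
  pot <- toy_lj(eps = 1, sigma = 2)
  cfg <- molecular_configuration(rep("X", 2),
                                 rbind(c(0, 0, 0), c(2, 0, 0)),
                                 masses = rep(1, 2))
  expect_equal(evaluate(pot, cfg)$energy, 0, tolerance = 1e-12)
  cfg$positions[2, 1] <- 2^(1 / 6) * 2
  expect_lt(max(abs(evaluate(pot, cfg)$forces)), 1e-10)
  # u' = -24 eps/sigma, u'' = 456 eps/sigma^2 at r = sigma
  pd <- pair_derivatives(pot, c("X", "X"), 2)
  expect_equal(pd$du, -24 * 1 / 2)
  expect_equal(pd$d2u, 456 * 1 / 4)
  # Coulomb power law: u = q^2 k / r
  potq <- toy_lj(eps = 0, sigma = 1, charge = 1)
  pdq <- pair_derivatives(potq, c("X", "X"), 2)
  expect_equal(pdq$du, -const$coulomb / 4)
  expect_equal(pdq$d2u, const$coulomb / 4)
  # derivative consistency against finite differences
  r <- 2.7; h <- 1e-6
  pd2 <- pair_derivatives(pot, c("X", "X"), c(r - h, r, r + h))
  expect_equal((pd2$u[3] - pd2$u[1]) / (2 * h), pd2$du[2], tolerance = 1e-6)
})

test_that("forces are the exact negative gradient on every kind", {
  cases <- list(
    list(pot = morse1d(D = 30, a = 1.2), cfg = config_1d(0.37)),
    list(pot = quartic1d(c = 10), cfg = config_1d(-0.8)),
    list(pot = toy_lj(charge = 0.3), cfg = toy_cluster()),
    list(pot = toywater3(), cfg = octamer_fixture()[[1]]))
  for (cs in cases) {
    ev <- evaluate(cs$pot, cs$cfg)
    nf <- numeric_force(cs$pot, cs$cfg)
    expect_lt(max(abs(nf - ev$forces)) / max(abs(ev$forces)), 1e-6)
  }
  # periodic fluid with shifted-force cutoff
  box <- make_fixtures("ljfluid_32", seed = 2)
  fluid <- periodic_pair_fluid(eps = 1, sigma = 2.8, cutoff = 6)
  ev <- evaluate(fluid, box)
  nf <- numeric_force(fluid, box)
  expect_lt(max(abs(nf - ev$forces)) / max(abs(ev$forces)), 1e-6)
})

test_that("translation-invariant potentials obey Newton's third law", {
  for (cs in list(list(pot = toy_lj(charge = 0.2), cfg = toy_cluster()),
                  list(pot = toywater3(), cfg = octamer_fixture()[[1]]))) {
    F <- evaluate(cs$pot, cs$cfg)$forces
    expect_lt(max(abs(colSums(F))), 1e-10)
  }
})

test_that("cluster energies are rigid-motion invariant and pair-decomposable", {
  pot <- toy_lj(charge = 0.3)
  cfg <- toy_cluster()
  e0 <- evaluate(pot, cfg)$energy
  shifted <- cfg; shifted$positions <- cfg$positions + rep(c(3, -2, 5), each = 4)
  expect_equal(evaluate(pot, shifted)$energy, e0, tolerance = 1e-12)
  rot <- cfg; rot$positions <- cfg$positions %*%
    t(mlcmd:::.random_rotation(seeded_rng(5)))
  expect_equal(evaluate(pot, rot)$energy, e0, tolerance = 1e-10)
  # energy equals the sum of pair_derivatives u(r) over all pairs
  idx <- combn(4, 2)
  r <- sqrt(rowSums((cfg$positions[idx[1, ], ] - cfg$positions[idx[2, ], ])^2))
  expect_equal(sum(pair_derivatives(pot, c("X", "X"), r)$u), e0,
               tolerance = 1e-10)
})

test_that("periodic systems respect minimum image and cutoff rules", {
  box <- make_fixtures("ljfluid_32", seed = 2)
  fluid <- periodic_pair_fluid(eps = 1, sigma = 2.8, cutoff = 6)
  e0 <- evaluate(fluid, box)$energy
  # translating one atom by a full lattice vector changes nothing
  moved <- box
  moved$positions[5, ] <- moved$positions[5, ] + box$cell
  expect_equal(evaluate(fluid, moved)$energy, e0, tolerance = 1e-9)
  # cutoff beyond half the box is rejected
  big <- periodic_pair_fluid(eps = 1, sigma = 2.8,
                             cutoff = min(box$cell))
  expect_error(evaluate(big, box), "cutoff")
  # uncovered species is a parameterization error
  alien <- box; alien$elements[1] <- "Y"
  alien$masses[1] <- 1
  expect_error(evaluate(fluid, alien), "species")
})
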