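test_that("physical constants are CODATA-consistent in internal units", {
  expect_equal(const$kB * 300, 2.49434, tolerance = 1e-3)   # kJ/mol at 300 K
  # hbar * omega for a 1 rad/fs oscillator is an energy; cross-check via
  # the SI route: 1.054571817e-34 J s * 1e15 /fs * NA / 1000
  expect_equal(const$hbar, 1.054571817e-34 * 1e15 * 6.02214076e23 / 1000,
               tolerance = 1e-12)
  # unit round-trip: kJ/mol -> J -> kJ/mol exact to 1e-12 relative
  x <- 17.3
  expect_equal(x * 1000 / 6.02214076e23 * 6.02214076e23 / 1000, x,
               tolerance = 1e-12)
  # 1 amu A^2/fs^2 = 1e4 kJ/mol underpins all kinetic terms
  expect_identical(mass_to_energy_units(1), 1e4)
  # wavenumber conversion round-trip
  expect_equal(angular_to_cm1(cm1_to_angular(670)), 670, tolerance = 1e-12)
})

test_that("seeded rng streams are reproducible and independent", {
  a <- rng_gauss(seeded_rng(0), 100)
  b <- rng_gauss(seeded_rng(0), 100)
  expect_identical(a, b)
  expect_false(any(rng_gauss(seeded_rng(1), 100) == a))
  # spawned child streams are mutually (nearly) uncorrelated
  parent <- seeded_rng(42)
  c1 <- rng_spawn(parent); c2 <- rng_spawn(parent)
  x <- rng_gauss(c1, 1e4); y <- rng_gauss(c2, 1e4)
  expect_lt(abs(cor(x, y)), 0.05)
  # drawing from a handle leaves the global RNG untouched
  set.seed(123); before <- .Random.seed
  invisible(rng_unif(seeded_rng(7), 10))
  expect_identical(.Random.seed, before)
})

test_that("configurations validate their invariants", {
  cfg <- molecular_configuration(c("O", "H", "H"),
                                 rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(cfg$masses, c(15.999, 1.008, 1.008))
  expect_error(molecular_configuration("Zz", matrix(0, 1, 3)),
               "unknown element")
  expect_error(molecular_configuration("H", matrix(c(NaN, 0, 0), 1)),
               "finite")
  expect_error(molecular_configuration("H", matrix(0, 1, 3),
                                       cell = c(5, -1, 5)), "positive")
  cfgX <- molecular_configuration("X", matrix(0, 1, 3), masses = 2.5)
  expect_equal(cfgX$masses, 2.5)
})

test_that("extended-XYZ I/O round-trips frames, species and cells", {
  tmp <- tempfile(fileext = ".xyz")
  cfg1 <- molecular_configuration(c("O", "H", "H"),
                                  rbind(c(0.1, 0.2, 0.3),
                                        c(1.05721, 0, 0),
                                        c(-0.3, 0.9, 0)))
  cfg2 <- molecular_configuration(rep("X", 2),
                                  rbind(c(0, 0, 0), c(2.5, 0, 0)),
                                  masses = c(X = 2), cell = c(10, 10, 10))
  write_xyz(list(cfg1, cfg2), tmp)
  back <- read_xyz(tmp, masses = c(X = 2))
  expect_length(back, 2)
  expect_identical(back[[1]]$elements, cfg1$elements)
  expect_lt(max(abs(back[[1]]$positions - cfg1$positions)), 1e-8)
  expect_true(back[[2]]$periodic)
  expect_equal(back[[2]]$cell, c(10, 10, 10))
})

test_that("xyz reader parses a hand-written lattice frame and flags errors", {
  tmp <- tempfile(fileext = ".xyz")
  writeLines(c(
    "3",
    'Lattice="10 0 0 0 10 0 0 0 10" Properties=species:S:1:pos:R:3 T=300',
    "O 0.0 0.0 0.0",
    "H 0.95 0.0 0.0",
    "H -0.25 0.92 0.0"), tmp)
  fr <- read_xyz(tmp)[[1]]
  expect_true(fr$periodic)
  expect_equal(fr$cell, c(10, 10, 10))
  expect_equal(attr(fr, "comment_fields")$T, "300")

  writeLines(c("2", "comment", "H 0 0 0", "H 0 zero 0"), tmp)
  expect_error(read_xyz(tmp), "line 4")
  writeLines(c("5", "comment", "H 0 0 0"), tmp)
  expect_error(read_xyz(tmp), "truncated")
})

test_that("record and model serialization round-trips", {
  g <- config_1d(0.4)
  mf <- matrix(c(-1.25, 0, 0), 1); cf <- matrix(c(-1.1, 0, 0), 1)
  rec <- centroid_force_record(g, mf, cf, meta = list(T = 300, P = 32))
  tmp <- tempfile(fileext = ".json")
  save_records(list(rec), tmp)
  back <- load_records(tmp)[[1]]
  expect_equal(back$delta_force, rec$delta_force, tolerance = 1e-12)
  expect_equal(back$geometry$positions, g$positions, tolerance = 1e-12)

  dp <- descriptor_params_1d(-1, 1, 5)
  mod <- random_correction_model(dp, hidden = c(4, 3), seed = 9)
  tmp2 <- tempfile(fileext = ".json")
  save_correction_model(mod, tmp2)
  mod2 <- load_correction_model(tmp2)
  x <- config_1d(0.3)
  expect_equal(predict(mod2, x), predict(mod, x), tolerance = 1e-12)
})
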