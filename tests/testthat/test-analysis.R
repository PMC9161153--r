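test_that("ideal-gas RDF is flat and a static dimer fills one bin", {
  rng <- seeded_rng(44)
  L <- 12
  frames <- lapply(1:40, function(i)
    molecular_configuration(rep("X", 40),
                            matrix(rng_unif(rng, 120) * L, 40, 3),
                            masses = c(X = 1), cell = rep(L, 3)))
  g <- rdf(frames, c("X", "X"), r_max = 5.5, n_bins = 25)
  # per-bin fluctuation scale from the expected Poisson pair counts
  meta <- attr(g, "meta")
  edges <- seq(0, 5.5, length.out = 26)
  lambda <- meta$n_frames * meta$n_pairs *
    (4 / 3 * pi * diff(edges^3)) / meta$V
  expect_true(all(abs(g$g - 1) < 3.5 / sqrt(lambda) + 0.05))
  # a fixed dimer at distance d populates exactly the bin containing d
  dimer <- molecular_configuration(rep("X", 2),
                                   rbind(c(0, 0, 0), c(3.3, 0, 0)),
                                   masses = c(X = 1), cell = rep(L, 3))
  gd <- rdf(list(dimer, dimer), c("X", "X"), r_max = 5, n_bins = 20)
  expect_equal(sum(gd$count), 2)
  expect_equal(which(gd$count > 0), findInterval(3.3, seq(0, 5, 0.25)))
  expect_error(rdf(frames, c("X", "X"), r_max = 7), "half the shortest")
})

test_that("RDF matches a naive double-loop histogram exactly", {
  rng <- seeded_rng(17)
  L <- 10
  frames <- lapply(1:5, function(i)
    molecular_configuration(rep("X", 12),
                            matrix(rng_unif(rng, 36) * L, 12, 3),
                            masses = c(X = 1), cell = rep(L, 3)))
  g <- rdf(frames, c("X", "X"), r_max = 4.5, n_bins = 15)
  counts <- numeric(15)
  edges <- seq(0, 4.5, length.out = 16)
  for (fr in frames) for (i in 1:11) for (j in (i + 1):12) {
    d <- fr$positions[i, ] - fr$positions[j, ]
    d <- d - round(d / L) * L
    r <- sqrt(sum(d^2))
    if (r < 4.5) {
      b <- findInterval(r, edges)
      counts[b] <- counts[b] + 1
    }
  }
  expect_identical(g$count, counts)
})

test_that("RDF integral equals the mean neighbour count within r_max", {
  rng <- seeded_rng(9)
  L <- 11
  frames <- lapply(1:8, function(i)
    molecular_configuration(rep("X", 20),
                            matrix(rng_unif(rng, 60) * L, 20, 3),
                            masses = c(X = 1), cell = rep(L, 3)))
  g <- rdf(frames, c("X", "X"), r_max = 5, n_bins = 20)
  meta <- attr(g, "meta")
  # same-binning identity: sum of counts / (frames * N) * 2 equals the
  # shell integral of rho g(r)
  edges <- seq(0, 5, length.out = 21)
  shell <- 4 / 3 * pi * diff(edges^3)
  lhs <- sum(g$g * shell) * (meta$n_pairs / meta$V) * 2 / meta$n_i
  rhs <- sum(g$count) / (meta$n_frames * meta$n_i) * 2
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("MSD diagnostics separate frozen, ballistic and diffusive motion", {
  # frozen configuration: D = 0
  cfg <- make_fixtures("ljfluid_32", seed = 5)
  frozen <- run_md(ideal_gas(), cfg, n_steps = 400, T = 100, seed = 2,
                   ensemble = "nve", stride = 10,
                   velocities = matrix(0, 32, 3))
  m <- msd_diffusion(frozen, dims = 3)
  expect_equal(m$D, 0, tolerance = 1e-12)
  # ballistic NVE free particle: MSD = v^2 t^2, flagged non-diffusive
  one <- molecular_configuration("X", matrix(0, 1, 3), masses = c(X = 1))
  bal <- run_md(ideal_gas(), one, n_steps = 1000, T = 300,
                ensemble = "nve", seed = 3, stride = 10)
  v2 <- sum(bal$velocity_frames[[1]]^2)
  mb <- msd_diffusion(bal, dims = 3)
  expect_false(mb$diffusive)
  expect_equal(mb$msd$msd, v2 * mb$msd$lag_fs^2, tolerance = 1e-8)
  # Langevin free particle is flagged diffusive with a sane D
  # (the quantitative 5% check lives with the dynamics tests)
  xs <- run_md_1d(free1d(mass = 1.008), T = 250, n_steps = 1e6, dt = 0.5,
                  friction = 0.01, stride = 40, seed = 6)
  fake <- structure(list(
    frames = lapply(xs, function(x) matrix(c(x, 0, 0), 1)),
    meta = list(dt = 0.5, stride = 40, elements = "H", masses = 1.008,
                cell = NULL, periodic = FALSE)), class = "md_trajectory")
  md <- msd_diffusion(fake, dims = 1, fit_window = c(600, 4000),
                      max_lag = 300)
  D_exp <- const$kB * 250 / (mass_to_energy_units(1.008) * 0.01) * 1000
  expect_true(md$diffusive)
  expect_lt(abs(md$D - D_exp) / D_exp, 0.35)
})
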