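test_that("network feature-gradient and parameter Jacobian are analytic", {
  rng <- seeded_rng(11)
  net <- mlcmd:::.net_random(7, c(5, 4), rng)
  f <- rng_gauss(rng, 7)
  st <- mlcmd:::.net_g(net, f)
  h <- 1e-6
  # g = d(net)/d(features) against finite differences
  for (q in seq_len(7)) {
    fp <- f; fp[q] <- fp[q] + h; fm <- f; fm[q] <- fm[q] - h
    fd <- (mlcmd:::.net_g(net, fp)$u - mlcmd:::.net_g(net, fm)$u) / (2 * h)
    expect_equal(st$g[q], fd, tolerance = 1e-6)
  }
  # dg/dtheta against finite differences over every parameter
  J <- mlcmd:::.net_g_jac(net, f)
  th <- mlcmd:::.net_pack(net)
  for (p in seq_along(th)) {
    tp <- th; tp[p] <- tp[p] + h; tm <- th; tm[p] <- tm[p] - h
    gp <- mlcmd:::.net_g(mlcmd:::.net_unpack(tp, 7, c(5, 4)), f)$g
    gm <- mlcmd:::.net_g(mlcmd:::.net_unpack(tm, 7, c(5, 4)), f)$g
    expect_lt(max(abs((gp - gm) / (2 * h) - J[, p])), 1e-7)
  }
})

test_that("predicted corrections are conservative and equivariant", {
  dp <- descriptor_params(elements = c("H", "O"))
  mod <- random_correction_model(dp, hidden = c(6, 6), seed = 21)
  cfg <- octamer_fixture()[[1]]
  dF <- predict(mod, cfg)
  # translation invariance of features implies zero net force
  expect_lt(max(abs(colSums(dF))), 1e-8)
  # rotating the configuration rotates the forces
  R <- mlcmd:::.random_rotation(seeded_rng(9))
  rot <- cfg; rot$positions <- cfg$positions %*% t(R)
  expect_lt(max(abs(predict(mod, rot) - dF %*% t(R))), 1e-8)
  # forces are the exact negative gradient of the model scalar
  h <- 1e-5
  for (probe in list(c(1, 1), c(5, 2), c(17, 3))) {
    cp <- cfg; cm <- cfg
    cp$positions[probe[1], probe[2]] <- cp$positions[probe[1], probe[2]] + h
    cm$positions[probe[1], probe[2]] <- cm$positions[probe[1], probe[2]] - h
    fd <- -(correction_scalar(mod, cp) - correction_scalar(mod, cm)) / (2 * h)
    expect_equal(dF[probe[1], probe[2]], fd, tolerance = 1e-4)
  }
})

test_that("correction locality: distant perturbations never reach an atom", {
  dp <- descriptor_params(elements = c("H", "O"))
  mod <- random_correction_model(dp, hidden = c(6, 6), seed = 33)
  base <- octamer_fixture()[[1]]
  # a remote molecule beyond cutoff + skin from the whole cluster
  cfg <- molecular_configuration(
    c(base$elements, "O", "H", "H"),
    rbind(base$positions,
          sweep(base$positions[1:3, ], 2, c(16, 0, 0), "+")))
  dF <- predict(mod, cfg)
  moved <- cfg
  moved$positions[25, ] <- moved$positions[25, ] + 0.4
  dF2 <- predict(mod, moved)
  # forces on the original cluster are bitwise unaffected
  expect_equal(dF2[1:24, ], dF[1:24, ], tolerance = 1e-12)
})

test_that("training on all-zero labels returns a null correction", {
  clusters <- octamer_fixture()
  recs <- lapply(clusters, function(cfg) {
    z <- matrix(0, nrow(cfg$positions), 3)
    centroid_force_record(cfg, z, z)
  })
  dp <- descriptor_params(elements = c("H", "O"))
  mod <- suppressWarnings(train_correction(recs, dp, hidden = c(4, 4),
                                           seed = 2, lm_maxit = 5))
  probe <- clusters[[1]]
  probe$positions <- probe$positions + 0.05
  expect_lt(sqrt(mean(predict(mod, probe)^2)), 1e-3)
})

test_that("seeded training is reproducible", {
  clusters <- octamer_fixture()
  dp <- descriptor_params(elements = c("H", "O"))
  teacher <- random_correction_model(dp, hidden = c(4, 4), seed = 50)
  recs <- lapply(clusters, function(cfg)
    centroid_force_record(cfg, predict(teacher, cfg),
                          matrix(0, nrow(cfg$positions), 3)))
  m1 <- suppressWarnings(train_correction(recs, dp, hidden = c(4, 4),
                                          seed = 7, lm_maxit = 5))
  m2 <- suppressWarnings(train_correction(recs, dp, hidden = c(4, 4),
                                          seed = 7, lm_maxit = 5))
  expect_identical(coef(m1), coef(m2))
  expect_identical(m1$meta$loss, m2$meta$loss)
})

test_that("training records fewer than two are rejected", {
  cfg <- octamer_fixture()[[1]]
  rec <- centroid_force_record(cfg, matrix(0, 24, 3), matrix(0, 24, 3))
  expect_error(train_correction(list(rec),
                                descriptor_params(elements = c("H", "O"))),
               "at least 2")
})
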