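test_that("features vanish without neighbours and respect the cutoff", {
  dp <- descriptor_params(elements = c("H", "O"))
  lone <- molecular_configuration("H", matrix(0, 1, 3))
  ft <- compute_features(lone, dp, gradients = TRUE)
  expect_true(all(ft$features == 0))
  expect_true(all(ft$grads[[1]]$grad == 0))
  # an atom beyond the cutoff contributes nothing
  pairc <- molecular_configuration(c("H", "H"),
                                   rbind(c(0, 0, 0), c(4.5, 0, 0)))
  expect_true(all(compute_features(pairc, dp)$features == 0))
  # smoothness: features go to zero continuously at r_c
  just_in <- molecular_configuration(c("H", "H"),
                                     rbind(c(0, 0, 0), c(3.999, 0, 0)))
  expect_lt(max(compute_features(just_in, dp)$features), 1e-4)
})

test_that("features are invariant under rotation, translation, permutation", {
  dp <- descriptor_params(elements = c("H", "O"))
  cfg <- octamer_fixture()[[1]]
  f0 <- compute_features(cfg, dp)$features
  rot <- cfg
  rot$positions <- cfg$positions %*% t(mlcmd:::.random_rotation(seeded_rng(8)))
  expect_lt(max(abs(compute_features(rot, dp)$features - f0)), 1e-10)
  sh <- cfg; sh$positions <- cfg$positions + rep(c(5, -3, 2), each = 24)
  expect_lt(max(abs(compute_features(sh, dp)$features - f0)), 1e-10)
  # permuting two whole molecules permutes the feature rows identically
  perm <- c(4:6, 1:3, 7:24)
  pm <- cfg
  pm$positions <- cfg$positions[perm, ]; pm$elements <- cfg$elements[perm]
  expect_lt(max(abs(compute_features(pm, dp)$features - f0[perm, ])), 1e-10)
})

test_that("feature gradients match central finite differences", {
  dp <- descriptor_params(elements = c("H", "O"))
  cfg <- octamer_fixture()[[1]]
  ft <- compute_features(cfg, dp, gradients = TRUE)
  h <- 1e-5
  for (a in c(1, 2)) {       # an O and an H environment
    gr <- ft$grads[[a]]
    for (ii in seq(1, length(gr$idx), by = 5)) for (k in 1:3) {
      cp <- cfg; cm <- cfg
      cp$positions[gr$idx[ii], k] <- cp$positions[gr$idx[ii], k] + h
      cm$positions[gr$idx[ii], k] <- cm$positions[gr$idx[ii], k] - h
      fd <- (compute_features(cp, dp)$features[a, ] -
             compute_features(cm, dp)$features[a, ]) / (2 * h)
      expect_lt(max(abs(fd - gr$grad[, ii, k])) / max(1, max(abs(fd))),
                1e-5)
    }
  }
})

test_that("locality: atoms beyond the cutoff cannot change a feature", {
  dp <- descriptor_params(elements = c("H", "O"))
  base <- octamer_fixture()[[1]]
  # append a remote molecule well beyond the cutoff from every atom
  cfg <- molecular_configuration(
    c(base$elements, "O", "H", "H"),
    rbind(base$positions,
          sweep(base$positions[1:3, ], 2, c(15, 0, 0), "+")))
  ft <- compute_features(cfg, dp)
  far <- 25:27
  expect_gt(min(sqrt(rowSums(sweep(cfg$positions[far, ], 2,
                                   cfg$positions[1, ])^2))), dp$cutoff)
  moved <- cfg
  moved$positions[far, ] <- moved$positions[far, ] +
    rep(c(0.5, -0.3, 0.2), each = 3)
  expect_equal(compute_features(moved, dp)$features[1, ], ft$features[1, ],
               tolerance = 1e-12)
})

test_that("coordinate-mode descriptors expose the 1D coordinate", {
  dp <- descriptor_params_1d(-2, 2, 9)
  ft <- compute_features(config_1d(0.5), dp, gradients = TRUE)
  expect_equal(dim(ft$features), c(1L, 9L))
  expect_equal(ft$features[1, ],
               exp(-0.5 * ((0.5 - dp$centers) / dp$width)^2),
               tolerance = 1e-12)
  # gradient only along x
  expect_true(all(ft$grads[[1]]$grad[, 1, 2:3] == 0))
  h <- 1e-6
  fd <- (compute_features(config_1d(0.5 + h), dp)$features[1, ] -
         compute_features(config_1d(0.5 - h), dp)$features[1, ]) / (2 * h)
  expect_equal(ft$grads[[1]]$grad[, 1, 1], fd, tolerance = 1e-6)
})

test_that("unknown elements are a parameterization error", {
  dp <- descriptor_params(elements = c("H", "O"))
  cfg <- molecular_configuration(c("H", "N"),
                                 rbind(c(0, 0, 0), c(1.2, 0, 0)))
  expect_error(compute_features(cfg, dp), "not parameterized")
})
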