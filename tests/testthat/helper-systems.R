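# shared fixtures and small utilities for the suite

const <- phys_constants()

# a tiny LJ + charge cluster potential with one toy species
toy_lj <- function(eps = 1, sigma = 2, charge = 0, mass = 1) {
  lj_coulomb_cluster(list(X = list(eps = eps, sigma = sigma,
                                   charge = charge, mass = mass)))
}

# an equilateral-ish 4-atom cluster configuration of species X
toy_cluster <- function(mass = 1) {
  pos <- rbind(c(0, 0, 0), c(2.2, 0, 0), c(1.1, 1.9, 0), c(1.1, 0.7, 1.8))
  molecular_configuration(rep("X", 4), pos, masses = rep(mass, 4))
}

# small toy-water octamer, deterministic (cached per session)
octamer_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      box <- make_fixtures("toywater_box_30", seed = 4, equil_steps = 400)
      traj <- run_md(toywater3(), box, n_steps = 200, T = 300, seed = 6,
                     stride = 100)
      cache <<- extract_clusters(traj, cluster_spec(), 2, seed = 2)
    }
    cache
  }
})

# discrete (finite-P) Matsubara width of a 1D harmonic ring polymer
width_discrete <- function(T, m_amu, omega_cm1, P) {
  beta <- 1 / (const$kB * T)
  m <- mass_to_energy_units(m_amu)
  om <- cm1_to_angular(omega_cm1)
  Om <- 2 * P * sin(pi * seq_len(P - 1) / P) / (beta * const$hbar)
  sum(1 / (Om^2 + om^2)) / (m * beta)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y), 1e-300), tol)
}
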