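#' Cluster extraction rule
#'
#' @param n_neighbors molecules around the centre (default 7, giving
#'   8-molecule clusters whose central molecule has a complete first
#'   solvation shell by construction).
#' @param atoms_per_molecule fixed per-molecule atom count (molecules
#'   are identified by this schema, no bond perception).
#' @return a \code{cluster_spec}.
#' @export
cluster_spec <- function(n_neighbors = 7, atoms_per_molecule = 3) {
  stopifnot(n_neighbors >= 1, atoms_per_molecule >= 1)
  structure(list(n_neighbors = n_neighbors,
                 atoms_per_molecule = atoms_per_molecule),
            class = "cluster_spec")
}

.molecule_centers <- function(pos, masses, apm) {
  nmol <- nrow(pos) / apm
  centers <- matrix(0, nmol, 3)
  for (m in seq_len(nmol)) {
    idx <- (m - 1) * apm + seq_len(apm)
    centers[m, ] <- colSums(pos[idx, , drop = FALSE] * masses[idx]) /
      sum(masses[idx])
  }
  centers
}

#' Extract molecular clusters from a bulk trajectory
#'
#' For each draw, picks a random frame and random centre molecule,
#' selects the \code{n_neighbors} nearest molecules by
#' centre-of-mass minimum-image distance, unwraps the cluster to the
#' contiguous image around the centre, and strips periodicity.
#'
#' @param traj bulk trajectory (\code{md_trajectory},
#'   \code{pimd_trajectory} or list of configurations).
#' @param spec a [cluster_spec()].
#' @param n_clusters number of clusters to draw.
#' @param rng a [seeded_rng()] (or \code{seed}).
#' @param seed integer seed used if \code{rng} is missing.
#' @param center optional fixed centre molecule index (otherwise
#'   random).
#' @return list of non-periodic [molecular_configuration()]s, each
#'   with \code{n_neighbors + 1} molecules (centre first).
#' @export
extract_clusters <- function(traj, spec = cluster_spec(), n_clusters,
                             rng = NULL, seed = 1, center = NULL) {
  if (is.null(rng)) rng <- seeded_rng(seed)
  fr <- .trajectory_frames(traj)
  if (is.null(fr$cell)) stop("cluster extraction expects a periodic bulk system")
  apm <- spec$atoms_per_molecule
  n <- length(fr$elements)
  if (n %% apm != 0) stop("atom count is not a multiple of atoms_per_molecule")
  nmol <- n %/% apm
  if (nmol < spec$n_neighbors + 1)
    stop("fewer than ", spec$n_neighbors + 1, " molecules in the system")
  masses <- .lookup_masses(fr$elements, fr$masses)
  out <- vector("list", n_clusters)
  for (c_i in seq_len(n_clusters)) {
    f <- rng_int(rng, 1, length(fr$frames))
    cm <- if (is.null(center)) rng_int(rng, 1, nmol) else center
    pos <- fr$frames[[f]]
    centers <- .molecule_centers(pos, masses, apm)
    d <- min_image(sweep(centers, 2, centers[cm, ]), fr$cell)
    dist <- sqrt(rowSums(d^2))
    dist[cm] <- -Inf                      # centre always first
    sel <- order(dist)[seq_len(spec$n_neighbors + 1)]
    atoms <- unlist(lapply(sel, function(m) (m - 1) * apm + seq_len(apm)))
    # unwrap each molecule to the image nearest the centre molecule
    newpos <- matrix(0, length(atoms), 3)
    for (k in seq_along(sel)) {
      m <- sel[k]
      idx <- (m - 1) * apm + seq_len(apm)
      shift <- min_image(matrix(centers[m, ] - centers[cm, ], 1), fr$cell) -
        (centers[m, ] - centers[cm, ])
      newpos[(k - 1) * apm + seq_len(apm), ] <-
        sweep(pos[idx, , drop = FALSE], 2, -as.vector(shift))
    }
    out[[c_i]] <- molecular_configuration(fr$elements[atoms], newpos,
                                          masses = masses[atoms])
  }
  out
}

#' Build a centroid-force training set
#'
#' Runs fixed-centroid PIMD on every cluster and collects the
#' resulting [centroid_force_record()]s; records whose force SEM
#' exceeds the tolerance are flagged, not dropped.
#'
#' @param clusters list of configurations (from [extract_clusters()]).
#' @param potential the PES.
#' @param T temperature, K.
#' @param P bead count (NULL for the temperature-based default).
#' @param n_steps sampling steps per cluster.
#' @param tolerance SEM convergence tolerance, kJ/(mol Angstrom).
#' @param seed integer base seed; each cluster gets an independent
#'   spawned stream.
#' @param ... further arguments to [sample_fixed_centroid()].
#' @return object of class \code{training_set}: list of records with a
#'   summary attribute (SEM distribution, convergence counts).
#' @export
build_training_set <- function(clusters, potential, T, P = NULL,
                               n_steps = 20000, tolerance = 0.2, seed = 1,
                               ...) {
  rng <- seeded_rng(seed)
  records <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    child <- rng_spawn(rng)
    records[[i]] <- tryCatch(
      withCallingHandlers(
        sample_fixed_centroid(clusters[[i]], potential, T, P = P,
                              n_steps = n_steps, tolerance = tolerance,
                              seed = rng_kernel_seed(child), ...),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(records[[i]], "error"))
      warning("cluster ", i, " failed: ", conditionMessage(records[[i]]))
  }
  ok <- !vapply(records, inherits, TRUE, "error")
  recs <- records[ok]
  sems <- vapply(recs, function(r) max(r$force_sem), 0)
  structure(recs,
            summary = list(n = length(recs), n_failed = sum(!ok),
                           n_converged = sum(vapply(recs, `[[`, TRUE,
                                                    "converged")),
                           sem_median = stats::median(sems),
                           sem_max = if (length(sems)) max(sems) else NA),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(paste0("<training_set: %d records (%d converged, %d failed), ",
                     "median SEM %.3g kJ/mol/A>\n"),
              s$n, s$n_converged, s$n_failed, s$sem_median))
  invisible(x)
}

# ---------------------------------------------------------------------------
# deterministic toy fixtures
# ---------------------------------------------------------------------------

#' Deterministic toy datasets
#'
#' Generates the package's test systems from a seed; nothing is ever
#' downloaded.  Registry:
#' \describe{
#'   \item{toywater_box_30}{30 toy-water molecules in a periodic box at
#'     0.997 g/ml, equilibrated briefly with classical MD at 300 K.}
#'   \item{octamers_50}{50 octamer clusters extracted from a short
#'     bulk toy-water trajectory.}
#'   \item{ljfluid_32}{32-atom periodic Lennard-Jones fluid
#'     configuration on a perturbed lattice.}
#'   \item{quartic_grid}{single-atom configurations on a centroid grid
#'     for the 1D quartic system.}
#' }
#'
#' @param name registry entry.
#' @param seed integer seed.
#' @param n_clusters,equil_steps tuning for the cluster fixtures.
#' @return the fixture object (see registry).
#' @export
make_fixtures <- function(name, seed = 1, n_clusters = 50,
                          equil_steps = 1500) {
  switch(name,
    toywater_box_30 = .fixture_water_box(30, seed, equil_steps),
    octamers_50 = {
      box <- .fixture_water_box(30, seed, equil_steps)
      traj <- run_md(toywater3(), box, n_steps = 600, T = 300,
                     rng = seeded_rng(seed + 1000L), stride = 20)
      extract_clusters(traj, cluster_spec(), n_clusters,
                       rng = seeded_rng(seed + 2000L))
    },
    ljfluid_32 = .fixture_lj_box(32, seed),
    quartic_grid = lapply(seq(-1, 1, length.out = 21),
                          function(x) config_1d(x, "H")),
    stop("unknown fixture name: ", name))
}

# random-orientation toy water molecules on a jittered lattice at
# liquid-water density, then a short classical equilibration
.fixture_water_box <- function(nmol, seed, equil_steps) {
  rng <- seeded_rng(seed)
  p <- toywater3_params()
  L <- (nmol * 18.015 / (0.60221408 * 0.997))^(1 / 3)
  nside <- ceiling(nmol^(1 / 3))
  sites <- as.matrix(expand.grid(x = seq_len(nside), y = seq_len(nside),
                                 z = seq_len(nside))) - 0.5
  sites <- sites * L / nside
  sites <- sites[order(rng_unif(rng, nrow(sites)))[seq_len(nmol)], ,
                 drop = FALSE]
  # reference molecule geometry (O at origin, bisector along +z)
  half <- toywater3_params()$theta0 / 2
  ref <- rbind(c(0, 0, 0),
               c(p$r0 * sin(half), 0, p$r0 * cos(half)),
               c(-p$r0 * sin(half), 0, p$r0 * cos(half)))
  pos <- matrix(0, 3 * nmol, 3)
  for (m in seq_len(nmol)) {
    R <- .random_rotation(rng)
    pos[(m - 1) * 3 + 1:3, ] <-
      sweep(ref %*% t(R), 2, sites[m, ] + 0.1 * rng_gauss(rng, 3), "+")
  }
  cfg <- molecular_configuration(rep(c("O", "H", "H"), nmol), pos,
                                 cell = rep(L, 3))
  if (equil_steps > 0) {
    traj <- run_md(toywater3(), cfg, n_steps = equil_steps, T = 300,
                   dt = 0.5, rng = rng, stride = equil_steps)
    cfg$positions <- traj$frames[[length(traj$frames)]]
  }
  cfg
}

.random_rotation <- function(rng) {
  # rotation from a normalized quaternion
  q <- rng_gauss(rng, 4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.fixture_lj_box <- function(n, seed, density = 0.012, eps = 1, sigma = 2.8) {
  rng <- seeded_rng(seed)
  L <- (n / density)^(1 / 3)
  nside <- ceiling(n^(1 / 3))
  sites <- as.matrix(expand.grid(seq_len(nside), seq_len(nside),
                                 seq_len(nside))) - 0.5
  sites <- sites * L / nside
  sites <- sites[order(rng_unif(rng, nrow(sites)))[seq_len(n)], ,
                 drop = FALSE]
  sites <- sites + 0.05 * matrix(rng_gauss(rng, 3 * n), n, 3)
  molecular_configuration(rep("X", n), sites, masses = c(X = 2.016),
                          cell = rep(L, 3))
}
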