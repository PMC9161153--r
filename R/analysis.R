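#' Radial distribution function
#'
#' Shell-volume-normalized pair histogram over trajectory frames,
#' computed on whatever coordinates the frames carry — for ML-CMD and
#' PIMD centroid trajectories that is the centroid RDF.
#'
#' @param traj an \code{md_trajectory}, a \code{pimd_trajectory}, or a
#'   list of periodic [molecular_configuration()]s.
#' @param pair character vector of two species labels.
#' @param r_max histogram range, Angstrom (at most half the shortest
#'   box edge).
#' @param n_bins number of bins.
#' @return object of class \code{rdf_result}: data frame with columns
#'   \code{r} (bin centres), \code{g}, \code{count}; attributes carry
#'   the normalization metadata.
#' @export
rdf <- function(traj, pair, r_max, n_bins = 60) {
  fr <- .trajectory_frames(traj)
  cell <- fr$cell
  if (is.null(cell)) stop("RDF needs a periodic trajectory")
  if (r_max > min(cell) / 2 + 1e-12)
    stop("r_max exceeds half the shortest box edge")
  ii <- which(fr$elements == pair[1])
  jj <- which(fr$elements == pair[2])
  if (!length(ii) || !length(jj)) stop("no atoms match the species pair")
  same <- pair[1] == pair[2]
  edges <- seq(0, r_max, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  for (x in fr$frames) {
    if (same) {
      d <- .pair_distances(x[ii, , drop = FALSE], NULL, cell)
    } else {
      d <- .pair_distances(x[ii, , drop = FALSE], x[jj, , drop = FALSE], cell)
    }
    d <- d[d < r_max]
    counts <- counts + tabulate(findInterval(d, edges), nbins = n_bins)
  }
  V <- prod(cell)
  n_pairs <- if (same) length(ii) * (length(ii) - 1) / 2
             else length(ii) * length(jj)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(n_bins + 1)]^3)
  g <- counts / (length(fr$frames) * n_pairs * shell / V)
  out <- data.frame(r = (edges[-1] + edges[-(n_bins + 1)]) / 2, g = g,
                    count = counts)
  attr(out, "meta") <- list(pair = pair, n_frames = length(fr$frames),
                            n_pairs = n_pairs, V = V, r_max = r_max,
                            same = same,
                            n_i = length(ii), n_j = length(jj))
  class(out) <- c("rdf_result", "data.frame")
  out
}

.pair_distances <- function(xi, xj, cell) {
  if (is.null(xj)) {
    n <- nrow(xi)
    if (n < 2) return(numeric())
    idx <- utils::combn(n, 2)
    d <- xi[idx[1, ], , drop = FALSE] - xi[idx[2, ], , drop = FALSE]
  } else {
    d <- xi[rep(seq_len(nrow(xi)), each = nrow(xj)), , drop = FALSE] -
         xj[rep(seq_len(nrow(xj)), times = nrow(xi)), , drop = FALSE]
  }
  d <- min_image(d, cell)
  sqrt(rowSums(d^2))
}

.trajectory_frames <- function(traj) {
  if (inherits(traj, "md_trajectory"))
    list(frames = traj$frames, elements = traj$meta$elements,
         cell = traj$meta$cell, dt_frame = traj$meta$dt * traj$meta$stride,
         masses = traj$meta$masses)
  else if (inherits(traj, "pimd_trajectory"))
    list(frames = traj$centroid_frames,
         elements = traj$state$elements, cell = traj$state$cell,
         dt_frame = traj$meta$dt * traj$meta$stride,
         masses = traj$state$masses)
  else if (is.list(traj) && length(traj) &&
           inherits(traj[[1]], "molecular_configuration"))
    list(frames = lapply(traj, `[[`, "positions"),
         elements = traj[[1]]$elements, cell = traj[[1]]$cell,
         dt_frame = NA_real_, masses = traj[[1]]$masses)
  else stop("unsupported trajectory object")
}

#' @export
plot.rdf_result <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r (Angstrom)",
                 ylab = "g(r)", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Mean-squared displacement and self-diffusion constant
#'
#' MSD over multiple time origins with the Einstein-relation diffusion
#' constant D = slope / (2 d) fitted on a stated lag window.
#' Coordinates are unwrapped by minimum-image displacement
#' accumulation when the trajectory is periodic and frames appear
#' wrapped; trajectories produced by [run_md()] are already unwrapped.
#'
#' @param traj an \code{md_trajectory} (or list of configurations plus
#'   \code{dt_frame}).
#' @param species optional species selection.
#' @param fit_window lag-time window (fs) for the linear fit; default
#'   the middle half of available lags.
#' @param dims dimensionality of the diffusive motion (3 for fluids, 1
#'   for 1D systems).
#' @param origin_stride take every so-many-th frame as a time origin.
#' @param max_lag cap on the number of lag frames (keeps the
#'   origins-times-lags work bounded on long trajectories).
#' @param unwrap accumulate minimum-image displacements first.
#' @param n_blocks blocks (over origins) for the uncertainty estimate.
#' @return list with \code{msd} (data frame lag_fs, msd), \code{D}
#'   (Angstrom^2/ps), \code{D_se}, \code{fit_window}, and a
#'   \code{diffusive} flag (FALSE when the fitted log-log slope is far
#'   from 1, e.g. ballistic motion).
#' @export
msd_diffusion <- function(traj, species = NULL, fit_window = NULL,
                          dims = 3, origin_stride = 5, max_lag = 400,
                          unwrap = FALSE, n_blocks = 5) {
  fr <- .trajectory_frames(traj)
  dtf <- fr$dt_frame
  if (!is.finite(dtf)) stop("trajectory carries no frame time spacing")
  sel <- if (is.null(species)) seq_along(fr$elements)
         else which(fr$elements %in% species)
  if (!length(sel)) stop("no atoms match the species selection")
  X <- lapply(fr$frames, function(x) x[sel, , drop = FALSE])
  nfr <- length(X)
  if (nfr < 4) stop("too few frames for an MSD")
  if (unwrap && !is.null(fr$cell)) {
    for (i in 2:nfr) {
      d <- min_image(X[[i]] - X[[i - 1]], fr$cell)
      X[[i]] <- X[[i - 1]] + d
    }
  }
  max_lag <- min(floor(nfr / 2), max_lag)
  lags <- seq_len(max_lag)
  origins <- seq(1, nfr - max_lag, by = max(origin_stride,
                                            (nfr - max_lag) %/% 400 + 1))
  msd_o <- matrix(0, length(origins), max_lag)
  for (oi in seq_along(origins)) {
    o <- origins[oi]
    x0 <- X[[o]]
    for (l in lags) {
      d <- X[[o + l]] - x0
      msd_o[oi, l] <- mean(rowSums(d[, seq_len(dims), drop = FALSE]^2))
    }
  }
  msd <- colMeans(msd_o)
  lag_fs <- lags * dtf
  if (is.null(fit_window))
    fit_window <- c(lag_fs[ceiling(max_lag / 4)], lag_fs[max_lag])
  inw <- lag_fs >= fit_window[1] & lag_fs <= fit_window[2]
  if (!any(inw)) stop("fit window outside the available lag range")
  fit <- stats::lm(msd[inw] ~ lag_fs[inw])
  D <- unname(stats::coef(fit)[2]) / (2 * dims) * 1000  # A^2/fs -> A^2/ps
  # block uncertainty over origins
  blocks <- cut(seq_along(origins), breaks = min(n_blocks, length(origins)),
                labels = FALSE)
  Db <- vapply(unique(blocks), function(b) {
    mb <- colMeans(msd_o[blocks == b, , drop = FALSE])
    unname(stats::coef(stats::lm(mb[inw] ~ lag_fs[inw]))[2]) / (2 * dims) * 1000
  }, 0)
  D_se <- stats::sd(Db) / sqrt(length(Db))
  # diffusive-regime diagnostic: log-log slope ~ 1
  pos <- inw & msd > 0
  slope_ll <- if (sum(pos) > 2)
    unname(stats::coef(stats::lm(log(msd[pos]) ~ log(lag_fs[pos])))[2])
  else NA_real_
  list(msd = data.frame(lag_fs = lag_fs, msd = msd), D = D, D_se = D_se,
       fit_window = fit_window, loglog_slope = slope_ll,
       diffusive = is.finite(slope_ll) && abs(slope_ll - 1) < 0.3)
}
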