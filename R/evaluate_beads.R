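# Bead-vectorized potential evaluation for PIMD: energies and forces
# for all P replicas at once.  The default method loops over beads;
# kinds with vectorizable pair structure provide fast paths.

evaluate_beads <- function(potential, elements, masses, Xarr, cell) {
  UseMethod("evaluate_beads")
}

#' @export
evaluate_beads.default <- function(potential, elements, masses, Xarr, cell) {
  P <- dim(Xarr)[1]; n <- dim(Xarr)[2]
  F <- array(0, dim(Xarr)); E <- 0
  for (k in seq_len(P)) {
    cfg <- molecular_configuration(elements, matrix(Xarr[k, , ], n, 3),
                                   masses = masses, cell = cell)
    ev <- evaluate(potential, cfg)
    F[k, , ] <- ev$forces
    E <- E + ev$energy
  }
  list(F = F, E = E)
}

#' @export
evaluate_beads.toywater3 <- function(potential, elements, masses, Xarr,
                                     cell) {
  p <- potential$params
  topo <- .toywater_topology(potential, elements)
  P <- dim(Xarr)[1]; n <- dim(Xarr)[2]
  periodic <- !is.null(cell)
  key <- paste0("bead_n", n, "_P", P)
  if (is.null(potential$cache[[key]])) {
    fidx <- function(idx) as.vector(outer(seq_len(P), (idx - 1) * P, "+"))
    qq1 <- .const$coulomb *
      ifelse(topo$qi_is_O, p$qO, p$qH) * ifelse(topo$qj_is_O, p$qO, p$qH)
    potential$cache[[key]] <- list(
      ih1 = fidx(topo$h1), ih2 = fidx(topo$h2), io = fidx(topo$o),
      ip = fidx(topo$pi), jp = fidx(topo$pj),
      oo = rep(topo$is_oo, each = P), qq = rep(qq1, each = P),
      pad = seq_len(P * n))
  }
  cc <- potential$cache[[key]]
  flat <- function(idx) matrix(Xarr[, idx, ], P * length(idx), 3)
  Ff <- matrix(0, P * n, 3)   # flattened (bead-fastest) forces
  E <- 0

  for (hcol in c("ih1", "ih2")) {
    ih <- cc[[hcol]]
    u <- matrix(Xarr[, if (hcol == "ih1") topo$h1 else topo$h2, ],
                P * topo$nmol, 3) - flat(topo$o)
    r <- sqrt(rowSums(u^2))
    E <- E + sum(0.5 * p$kb * (r - p$r0)^2)
    fh <- -p$kb * (r - p$r0) / r * u
    Ff[ih, ] <- Ff[ih, ] + fh
    Ff[cc$io, ] <- Ff[cc$io, ] - fh
  }

  u <- flat(topo$h1) - flat(topo$o)
  v <- flat(topo$h2) - flat(topo$o)
  ru <- sqrt(rowSums(u^2)); rv <- sqrt(rowSums(v^2))
  cth <- pmin(1, pmax(-1, rowSums(u * v) / (ru * rv)))
  th <- acos(cth)
  sth <- pmax(sqrt(1 - cth^2), 1e-12)
  E <- E + sum(0.5 * p$ka * (th - p$theta0)^2)
  dEdth <- p$ka * (th - p$theta0)
  dth_du <- (cth / ru^2 * u - v / (ru * rv)) / sth
  dth_dv <- (cth / rv^2 * v - u / (ru * rv)) / sth
  Ff[cc$ih1, ] <- Ff[cc$ih1, ] - dEdth * dth_du
  Ff[cc$ih2, ] <- Ff[cc$ih2, ] - dEdth * dth_dv
  Ff[cc$io, ] <- Ff[cc$io, ] + dEdth * (dth_du + dth_dv)

  if (length(cc$ip)) {
    d <- flat(topo$pi) - flat(topo$pj)
    if (periodic) d <- min_image(d, cell)
    r <- sqrt(rowSums(d^2))
    qq <- cc$qq; oo <- cc$oo
    u_lj <- du_lj <- numeric(length(r))
    u_lj[oo] <- .lj_u(p$eps, p$sigma, r[oo])
    du_lj[oo] <- .lj_du(p$eps, p$sigma, r[oo])
    u_c <- qq / r
    du_c <- -qq / r^2
    if (periodic) {
      rc <- potential$cutoff
      if (rc > min(cell) / 2 + 1e-12)
        stop("cutoff exceeds half the shortest box edge")
      urc_lj <- durc_lj <- numeric(length(r))
      urc_lj[oo] <- .lj_u(p$eps, p$sigma, rc)
      durc_lj[oo] <- .lj_du(p$eps, p$sigma, rc)
      urc_c <- qq / rc
      durc_c <- -qq / rc^2
      inside <- r < rc
      upair <- ((u_lj - urc_lj - durc_lj * (r - rc)) +
                (u_c - urc_c - durc_c * (r - rc))) * inside
      dupair <- ((du_lj - durc_lj) + (du_c - durc_c)) * inside
    } else {
      upair <- u_lj + u_c
      dupair <- du_lj + du_c
    }
    E <- E + sum(upair)
    fv <- -dupair / r * d
    # scatter-add with every flat index present, so rowsum returns a
    # dense (P n) x 3 block in index order without name lookups
    acc <- rowsum(rbind(fv, -fv, matrix(0, P * n, 3)),
                  c(cc$ip, cc$jp, cc$pad))
    Ff <- Ff + acc
  }
  list(F = array(Ff, c(P, n, 3)), E = E)
}
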