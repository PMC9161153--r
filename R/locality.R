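#' Ring-polymer bead-distribution width from the Matsubara-mode sum
#'
#' In a locally harmonic potential the imaginary-time path fluctuates
#' around its centroid in independent Gaussian Matsubara modes
#' (frequencies 2 pi n / beta hbar), giving the closed-form second
#' moment per Cartesian degree of freedom
#' \deqn{\langle x^2\rangle = \frac{\beta\hbar^2}{2\pi^2 m}
#'   \left[-\frac{1}{2t^2} + \frac{\pi}{2t}\coth(\pi t)\right],
#'   \quad t = \frac{\beta\hbar\omega}{2\pi},}
#' where omega = sqrt(U''/m) is the intrinsic frequency of the mode.
#' The free-particle limit (omega = 0) is hbar^2 beta / 12 m, the
#' Gaussian-smearing width of the Feynman-Hibbs kernel; the zero-
#' temperature limit is hbar / 2 m omega, the quantum-harmonic-
#' oscillator ground-state variance.  Both limits are rigorous upper
#' bounds at all temperatures.
#'
#' @param T temperature(s), K.
#' @param m mass, amu.
#' @param omega_cm1 intrinsic frequency, cm^-1 (0 gives the
#'   free-particle limit).
#' @param method \code{"closed"} for the closed form (coth evaluated in
#'   an overflow-safe form), \code{"sum"} for independent direct
#'   summation of the Matsubara series with an arctangent tail
#'   correction (a cross-check, not for production).
#' @param n_terms number of explicit terms for \code{method = "sum"}.
#' @return second moment(s) in Angstrom^2.
#' @examples
#' matsubara_width(300, 1.008, 670)   # ~0.0115 A^2, rms ~0.107 A
#' fhc_width(300, 1.008)              # free-particle bound, ~0.0134 A^2
#' qho_width(1.008, 670)              # ground-state bound, ~0.0250 A^2
#' @export
matsubara_width <- function(T, m, omega_cm1, method = c("closed", "sum"),
                            n_terms = 1e6) {
  method <- match.arg(method)
  if (any(T <= 0) || m <= 0 || any(omega_cm1 < 0))
    stop("need T > 0, m > 0, omega >= 0")
  beta <- beta_of(T)
  m_int <- mass_to_energy_units(m)
  omega <- cm1_to_angular(omega_cm1)
  t <- beta * .const$hbar * omega / (2 * pi)
  pref <- beta * .const$hbar^2 / (2 * pi^2 * m_int)
  if (method == "closed") {
    out <- ifelse(t < 1e-8,
                  # analytic omega -> 0 limit: pi^2/6 bracket
                  pref * pi^2 / 6,
                  pref * (-1 / (2 * t^2) + (pi / (2 * t)) * .coth(pi * t)))
    return(out)
  }
  # direct summation: <x^2> = (beta hbar^2 / 4 pi^2 m) sum_{n!=0} 1/(n^2+t^2),
  # explicit terms to n_terms, remainder by the midpoint arctan integral
  tv <- rep_len(t, length(T)); pv <- rep_len(pref, length(T))
  vapply(seq_along(tv), function(i) {
    ti <- tv[i]
    n <- seq_len(n_terms)
    s <- 2 * sum(1 / (n^2 + ti^2))
    tail <- if (ti > 1e-300) 2 * (pi / 2 - atan((n_terms + 0.5) / ti)) / ti
            else 2 / (n_terms + 0.5)
    pv[i] / 2 * (s + tail)
  }, numeric(1))
}

# coth without overflow for large arguments: coth(z) = 1 + 2/(e^{2z}-1)
.coth <- function(z) 1 + 2 / expm1(2 * z)

#' @rdname matsubara_width
#' @return \code{fhc_width}: the free-particle (Feynman-Hibbs) bound
#'   hbar^2 / 12 m k T, Angstrom^2.
#' @export
fhc_width <- function(T, m) {
  if (any(T <= 0) || m <= 0) stop("need T > 0, m > 0")
  beta_of(T) * .const$hbar^2 / (12 * mass_to_energy_units(m))
}

#' @rdname matsubara_width
#' @return \code{qho_width}: the harmonic-oscillator ground-state bound
#'   hbar / 2 m omega, Angstrom^2.
#' @export
qho_width <- function(m, omega_cm1) {
  if (m <= 0 || any(omega_cm1 <= 0)) stop("need m > 0, omega > 0")
  .const$hbar / (2 * mass_to_energy_units(m) * cm1_to_angular(omega_cm1))
}

#' Relative quantum force-correction bound at a pair distance
#'
#' For two atoms interacting through a Coulombic (slowest-decaying)
#' force at separation R, the second-order bound on the relative
#' quantum correction to the force magnitude is
#' (3/R^2)(<x_i^2> + <x_j^2> - 2<x_i x_j>).  Dropping the (positive,
#' decaying) cross-correlation gives (3/R^2)(<x_i^2> + <x_j^2>);
#' bounding the correlation by Cauchy-Schwarz instead gives the
#' worst case 12 max(<x^2>) / R^2.
#'
#' @param R separation, Angstrom (> 0).
#' @param x2_i,x2_j bead-distribution second moments, Angstrom^2.
#' @param drop_correlation if TRUE, set the cross term to zero;
#'   otherwise use the Cauchy-Schwarz worst case.
#' @return dimensionless relative bound (multiply by 100 for percent).
#' @examples
#' w <- matsubara_width(300, 1.008, 670)
#' force_correction_bound(4, w, w, drop_correlation = TRUE)  # ~0.0043
#' force_correction_bound(4, qho_width(1.008, 670),
#'                        qho_width(1.008, 670))             # ~0.0187
#' @export
force_correction_bound <- function(R, x2_i, x2_j, drop_correlation = FALSE) {
  if (any(R <= 0)) stop("R must be positive")
  if (any(x2_i < 0) || any(x2_j < 0)) stop("second moments must be >= 0")
  if (drop_correlation) 3 / R^2 * (x2_i + x2_j)
  else 12 * pmax(x2_i, x2_j) / R^2
}

#' Width profile over a temperature grid
#'
#' Tabulates the Matsubara-mode width alongside its free-particle
#' (Feynman-Hibbs) and harmonic-oscillator bounds, suitable for
#' plotting against measured PIMD bead widths.
#'
#' @param T_grid temperatures, K (default 100 to 500).
#' @param m mass, amu.
#' @param omega_cm1 intrinsic frequency, cm^-1.
#' @return object of class \code{width_profile}: a data frame with
#'   columns T, t (dimensionless), x2, fhc, qho, rms.
#' @export
width_profile <- function(T_grid = seq(100, 500, by = 10), m = 1.008,
                          omega_cm1 = 670) {
  if (!length(T_grid)) stop("empty temperature grid")
  x2 <- matsubara_width(T_grid, m, omega_cm1)
  out <- data.frame(T = T_grid,
                    t = beta_of(T_grid) * .const$hbar *
                        cm1_to_angular(omega_cm1) / (2 * pi),
                    x2 = x2,
                    fhc = fhc_width(T_grid, m),
                    qho = qho_width(m, omega_cm1),
                    rms = sqrt(x2))
  attr(out, "m") <- m
  attr(out, "omega_cm1") <- omega_cm1
  class(out) <- c("width_profile", "data.frame")
  out
}

#' @export
plot.width_profile <- function(x, ...) {
  ylim <- range(0, sqrt(x$fhc), sqrt(x$qho), x$rms)
  graphics::plot(x$T, x$rms, type = "l", lwd = 2, ylim = ylim,
                 xlab = "T (K)", ylab = "rms bead width (Angstrom)", ...)
  graphics::lines(x$T, sqrt(x$fhc), lty = 2, col = "red")
  graphics::lines(x$T, sqrt(x$qho), lty = 3, col = "blue")
  graphics::legend("topright", c("Matsubara", "free-particle bound",
                                 "QHO bound"),
                   lty = 1:3, col = c("black", "red", "blue"), bty = "n")
  invisible(x)
}
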