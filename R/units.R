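#' Physical constants in internal units
#'
#' The package works in a single internal unit system throughout:
#' length in Angstrom, time in femtoseconds, mass in atomic mass units
#' (amu), energy in kJ/mol and temperature in Kelvin.  All public APIs
#' accept and return values in these units; conversion happens only at
#' I/O boundaries.
#'
#' Because 1 amu Angstrom^2/fs^2 equals 1e4 kJ/mol, mechanical formulas
#' written with masses in kJ/mol fs^2/Angstrom^2 need no stray factors.
#' [mass_to_energy_units()] performs that conversion; the constants
#' below are already expressed so that e.g. \code{hbar * omega} (omega
#' in rad/fs) is an energy in kJ/mol.
#'
#' @return A named list with elements
#'   \describe{
#'     \item{kB}{Boltzmann constant, kJ/(mol K).}
#'     \item{hbar}{Reduced Planck constant, kJ fs / mol.}
#'     \item{coulomb}{e^2/(4 pi eps0), kJ/mol Angstrom per unit charge pair.}
#'     \item{mass_energy}{kJ/mol per amu Angstrom^2/fs^2 (= 1e4).}
#'     \item{pressure_bar}{bar per kJ/mol/Angstrom^3.}
#'     \item{c_cm_fs}{speed of light in cm/fs (for wavenumber conversion).}
#'   }
#' @examples
#' const <- phys_constants()
#' const$kB * 300  # thermal energy at 300 K, about 2.494 kJ/mol
#' @export
phys_constants <- function() {
  list(
    kB = 0.00831446261815324,       # CODATA R / 1000
    hbar = 63.507799235029601,       # 1.054571817e-34 J s * NA -> kJ fs / mol
    coulomb = 1389.3545764438197,   # e^2/(4 pi eps0) in kJ/mol Angstrom
    mass_energy = 1e4,              # amu A^2/fs^2 -> kJ/mol
    pressure_bar = 16605.390671738467, # kJ/mol/A^3 -> bar
    c_cm_fs = 2.99792458e-5         # speed of light, cm per fs
  )
}

.const <- phys_constants()

#' Convert a mass from amu to internal energy-consistent units
#'
#' Returns the mass expressed in kJ/mol fs^2/Angstrom^2, so that
#' \code{0.5 * m * v^2} with v in Angstrom/fs is directly an energy in
#' kJ/mol.
#'
#' @param m_amu mass in amu.
#' @return mass in kJ/mol fs^2/Angstrom^2.
#' @export
mass_to_energy_units <- function(m_amu) m_amu * .const$mass_energy

#' Convert a vibrational wavenumber to angular frequency
#'
#' @param nu_cm1 wavenumber in cm^-1 (spectroscopy convention).
#' @return angular frequency in rad/fs.
#' @examples
#' cm1_to_angular(670)  # librational mode of H in water, ~0.126 rad/fs
#' @export
cm1_to_angular <- function(nu_cm1) 2 * pi * .const$c_cm_fs * nu_cm1

#' @rdname cm1_to_angular
#' @param omega angular frequency in rad/fs.
#' @export
angular_to_cm1 <- function(omega) omega / (2 * pi * .const$c_cm_fs)

# inverse temperature in mol/kJ
beta_of <- function(T) {
  if (any(T <= 0)) stop("temperature must be positive")
  1 / (.const$kB * T)
}
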