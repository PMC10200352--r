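#' @title Internal unit system and physical constants
#'
#' @description
#' All internal quantities are kept in Hartree atomic units with atomic
#' masses in amu: lengths in Bohr, energies in Hartree, charges in units of
#' the elementary charge.  File I/O uses Angstrom and spectra are reported
#' in cm^-1.  Every conversion factor is derived at load time from CODATA
#' 2018 fundamental constants, so there is exactly one place where a
#' physical number enters the package.
#'
#' @details
#' Derived quantities:
#' \itemize{
#'   \item \code{bohr_ang}: Bohr radius in Angstrom, from
#'     \eqn{a_0 = 4\pi\epsilon_0\hbar^2/(m_e e^2)}.
#'   \item \code{freq_cm1}: multiply \eqn{\sqrt{|\lambda|}} of a
#'     mass-weighted Hessian eigenvalue \eqn{\lambda} (Hartree/(amu Bohr^2))
#'     by this factor to get a wavenumber in cm^-1.
#'   \item \code{ir_km_mol}: converts a squared dipole derivative
#'     \eqn{(\partial\mu/\partial Q)^2} in e^2/amu to an integrated IR
#'     absorption intensity in km/mol,
#'     \eqn{A = N_A (\partial\mu/\partial Q)^2 / (12 \epsilon_0 c^2)}.
#'     The absolute radiation prefactor of the Einstein absorption
#'     coefficient is deliberately folded into this documented convention;
#'     relative intensities are the contract.
#'   \item \code{raman_ang4_amu}: converts a Raman activity from
#'     Bohr^4/amu to the conventional Angstrom^4/amu.
#' }
#' @return Named list of constants (all numeric scalars).
#' @examples
#' uc <- unit_constants()
#' uc$bohr_ang           # ~0.52918
#' @export
unit_constants <- function() .qmmvib_const

# CODATA 2018 inputs (SI). h, c, e, N_A are exact by definition.
.qmmvib_codata <- list(
  h    = 6.62607015e-34,     # J s
  c    = 299792458,          # m / s
  e    = 1.602176634e-19,    # C
  na   = 6.02214076e23,      # 1 / mol
  me   = 9.1093837015e-31,   # kg
  amu  = 1.66053906660e-27,  # kg
  eps0 = 8.8541878128e-12    # F / m
)

.qmmvib_derive_constants <- function(cd) {
  hbar <- cd$h / (2 * pi)
  a0 <- 4 * pi * cd$eps0 * hbar^2 / (cd$me * cd$e^2)     # m
  hartree <- hbar^2 / (cd$me * a0^2)                     # J
  list(
    hbar_si = hbar,
    bohr_m = a0,
    hartree_j = hartree,
    bohr_ang = a0 * 1e10,
    ang_bohr = 1 / (a0 * 1e10),
    # sqrt(Hartree / (amu Bohr^2)) -> cm^-1
    freq_cm1 = sqrt(hartree / (cd$amu * a0^2)) / (2 * pi * cd$c) / 100,
    # (e^2 / amu) -> km/mol
    ir_km_mol = cd$na * (cd$e^2 / cd$amu) / (12 * cd$eps0 * cd$c^2) / 1000,
    raman_ang4_amu = (a0 * 1e10)^4,
    codata = cd
  )
}

.qmmvib_const <- .qmmvib_derive_constants(.qmmvib_codata)

#' Angstrom to Bohr
#' @param x length(s) in Angstrom
#' @return length(s) in Bohr
#' @export
ang_to_bohr <- function(x) x * .qmmvib_const$ang_bohr

#' Bohr to Angstrom
#' @param x length(s) in Bohr
#' @return length(s) in Angstrom
#' @export
bohr_to_ang <- function(x) x * .qmmvib_const$bohr_ang

#' Squared harmonic 0->1 transition matrix element of a normal coordinate
#'
#' \eqn{|\langle 0|Q|1\rangle|^2 = \hbar/(2\omega)} for a harmonic
#' oscillator of angular frequency \eqn{\omega}, expressed in internal
#' normal-coordinate units (amu Bohr^2).  Used to scale Raman activities.
#'
#' @param freq_cm1 mode wavenumber in cm^-1 (must be > 0)
#' @return numeric, amu Bohr^2
#' @export
q01_squared <- function(freq_cm1) {
  if (any(freq_cm1 <= 0))
    stop("q01_squared() requires positive wavenumbers")
  uc <- .qmmvib_const
  omega_si <- 2 * pi * uc$codata$c * freq_cm1 * 100
  (uc$hbar_si / (2 * omega_si)) / (uc$codata$amu * uc$bohr_m^2)
}
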