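# Per-mode IR intensities and (resonance) Raman activities in the double
# harmonic approximation: dipole and polarizability expansions truncated at
# linear order along each normal mode.

#' Double-harmonic IR intensity
#'
#' Raw intensity per mode:
#' \eqn{(\partial\mu_x/\partial Q)^2 + (\partial\mu_y/\partial Q)^2 +
#' (\partial\mu_z/\partial Q)^2} in internal units (e^2/amu).  The km/mol
#' value multiplies by the conventional conversion constant (derived from
#' CODATA constants, see [unit_constants()]); the absolute radiation
#' prefactor of the absorption coefficient is folded into that constant and
#' relative intensities are the contract.
#'
#' @param dmu_dQ a 3-vector (single mode) or 3N x 3 matrix (one row per
#'   mode) of dipole derivatives in e/sqrt(amu)
#' @return data.frame with columns `raw` (e^2/amu) and `km_mol`
#' @export
ir_intensity <- function(dmu_dQ) {
  if (is.null(dim(dmu_dQ))) {
    stopifnot(length(dmu_dQ) == 3L)
    dmu_dQ <- matrix(dmu_dQ, 1L, 3L)
  }
  stopifnot(ncol(dmu_dQ) == 3L)
  raw <- rowSums(Mod(dmu_dQ)^2)
  data.frame(raw = raw, km_mol = raw * unit_constants()$ir_km_mol)
}

#' Raman invariants of a (transition) polarizability derivative tensor
#'
#' Isotropic invariant \eqn{\bar\alpha' = (\alpha'_{xx} + \alpha'_{yy} +
#' \alpha'_{zz})/3} and anisotropy
#' \eqn{\beta'^2 = \frac{1}{2}[(\alpha'_{xx}-\alpha'_{yy})^2 +
#' (\alpha'_{yy}-\alpha'_{zz})^2 + (\alpha'_{zz}-\alpha'_{xx})^2 +
#' 6(\alpha'^2_{xy} + \alpha'^2_{xz} + \alpha'^2_{yz})]}.
#' For complex (damped resonance) tensors every squared term is a squared
#' modulus.
#'
#' @param dalpha_dQ 3 x 3 (complex) tensor of polarizability derivatives
#'   along one mode
#' @param tol relative symmetry tolerance; asymmetry above it is an error
#' @return list with `a_iso` (complex scalar) and `b2` (real, >= 0)
#' @export
raman_invariants <- function(dalpha_dQ, tol = 1e-8) {
  a <- as.matrix(dalpha_dQ)
  stopifnot(all(dim(a) == c(3L, 3L)))
  scale <- max(1, max(Mod(a)))
  if (max(Mod(a - t(a))) > tol * scale)
    stop("polarizability derivative tensor is not symmetric (asymmetry ",
         format(max(Mod(a - t(a))), digits = 3), ")")
  a_iso <- (a[1, 1] + a[2, 2] + a[3, 3]) / 3
  b2 <- 0.5 * (Mod(a[1, 1] - a[2, 2])^2 + Mod(a[2, 2] - a[3, 3])^2 +
               Mod(a[3, 3] - a[1, 1])^2 +
               6 * (Mod(a[1, 2])^2 + Mod(a[1, 3])^2 + Mod(a[2, 3])^2))
  list(a_iso = a_iso, b2 = b2)
}

#' Raman scattering factor (activity) of a mode
#'
#' \eqn{S = 45\bar\alpha'^2 + 7\beta'^2} on the invariants of the
#' polarizability derivative tensor (squared moduli for complex input).
#' Unscaled activities are reported in the conventional Angstrom^4/amu.
#' The scaled variant multiplies the squared transition moments by the
#' harmonic 0->1 matrix element \eqn{|\langle 0|Q|1\rangle|^2 =
#' \hbar/(2\omega)}, i.e. \eqn{S_\mathrm{scaled} = S \cdot \hbar/(2\omega)}
#' in consistent units (reported in Angstrom^6).
#'
#' @param invariants a [raman_invariants()] result (internal units,
#'   Bohr^2/sqrt(amu) derivatives)
#' @param frequency mode wavenumber in cm^-1; required (positive) when
#'   `scaled = TRUE`
#' @param scaled multiply by the squared 0->1 transition matrix element?
#' @return numeric activity S
#' @export
raman_activity <- function(invariants, frequency = NULL, scaled = FALSE) {
  uc <- unit_constants()
  s_internal <- 45 * Mod(invariants$a_iso)^2 + 7 * invariants$b2
  if (!scaled) return(s_internal * uc$raman_ang4_amu)
  if (is.null(frequency) || frequency <= 0)
    stop("scaled Raman activity requires a positive mode frequency")
  s_internal * q01_squared(frequency) * uc$bohr_ang^6
}

#' Resonance Raman activity from a damped complex polarizability derivative
#'
#' Resonance and normal Raman scattering follow the same method: the
#' invariant formulas applied to the (now complex) polarizability
#' derivatives obtained at incident frequency \eqn{\omega} with damping
#' \eqn{\Gamma}.  At \eqn{\omega = 0} this reduces exactly to the static
#' activity.
#'
#' @param dalpha_dQ 3 x 3 complex tensor at the requested
#'   (\eqn{\omega, \Gamma})
#' @param frequency mode wavenumber in cm^-1 (for scaling)
#' @param scaled see [raman_activity()]
#' @param tol symmetry tolerance passed to [raman_invariants()]
#' @return numeric activity S
#' @export
resonance_raman_activity <- function(dalpha_dQ, frequency = NULL,
                                     scaled = FALSE, tol = 1e-8) {
  raman_activity(raman_invariants(dalpha_dQ, tol = tol),
                 frequency = frequency, scaled = scaled)
}

#' Assemble per-mode spectral peaks
#'
#' Combines a mode set and mode derivatives into one table of stick
#' spectra: frequency, IR intensity and Raman activities per mode.  Scaled
#' Raman activities are reported as NA for modes at or below zero frequency
#' (the 0->1 matrix element diverges).
#'
#' @param modes a [normal_modes()] result
#' @param mode_derivs a [project_to_modes()] result
#' @param ir,raman which intensity blocks to compute
#' @param omega,gamma radiation frequency and damping (Hartree) recorded as
#'   flags; `omega > 0` marks a resonance calculation
#' @return data.frame of class `spectrum_peaks` with columns `mode`,
#'   `frequency`, `ir_raw`, `ir_km_mol`, `raman_unscaled`, `raman_scaled`;
#'   attributes `omega`, `gamma`, `resonance`
#' @export
spectrum_peaks <- function(modes, mode_derivs, ir = TRUE, raman = TRUE,
                           omega = 0, gamma = 0.006) {
  stopifnot(inherits(modes, "mode_set"),
            inherits(mode_derivs, "mode_derivatives"))
  nm <- length(modes$frequencies)
  out <- data.frame(mode = seq_len(nm), frequency = modes$frequencies,
                    ir_raw = NA_real_, ir_km_mol = NA_real_,
                    raman_unscaled = NA_real_, raman_scaled = NA_real_)
  if (ir) {
    if (is.null(mode_derivs$dmu_dQ))
      stop("IR intensities requested but the bundle has no dipole derivatives")
    ii <- ir_intensity(mode_derivs$dmu_dQ)
    out$ir_raw <- ii$raw
    out$ir_km_mol <- ii$km_mol
  }
  if (raman) {
    if (is.null(mode_derivs$dalpha_dQ))
      stop("Raman activities requested but the bundle has no ",
           "polarizability derivatives")
    for (i in seq_len(nm)) {
      inv <- raman_invariants(mode_derivs$dalpha_dQ[i, , ])
      out$raman_unscaled[i] <- raman_activity(inv)
      out$raman_scaled[i] <- if (out$frequency[i] > 0)
        raman_activity(inv, out$frequency[i], scaled = TRUE)
      else NA_real_
    }
  }
  attr(out, "omega") <- omega
  attr(out, "gamma") <- gamma
  attr(out, "resonance") <- omega > 0
  class(out) <- c("spectrum_peaks", "data.frame")
  out
}
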