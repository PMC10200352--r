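# Finite-difference derivative sweep, normal modes, chain-rule projection
# and isotope restarts.
#
# Displacements are applied in plain Cartesian coordinates (default step
# 0.01 Bohr); mass weighting is applied analytically afterwards.  That
# choice is what makes isotope restarts possible from a stored sweep:
# the Cartesian second derivatives are mass-independent, so amending the
# atomic masses re-derives every frequency and intensity with zero new
# single-point calculations.

#' Finite-difference derivative sweep
#'
#' For each of the 3N Cartesian coordinates of the vibrationally active
#' atoms, evaluates the calculator at +step and -step displacements (6N
#' single points in total; the embedding scheme is applied at every
#' displaced geometry) and forms two-point central differences: Hessian
#' columns from gradients, dipole and polarizability derivative rows from
#' the respective properties.  The single points are dispatched over
#' `workgroups` groups of coordinates; aggregation order is fixed by
#' coordinate index, so the result is bit-identical for any group count.
#'
#' @param calc a calculator providing gradients (plus dipole /
#'   polarizability as requested)
#' @param struct the reference geometry
#' @param rmap a [region_map()]; default treats all atoms as inner and
#'   vibrationally active
#' @param step displacement in Bohr (default 0.01)
#' @param workgroups number of work groups M >= 1
#' @param dipole compute dipole derivatives?
#' @param polarizability compute polarizability derivatives?
#' @param omega,gamma radiation frequency and damping (Hartree) passed to
#'   the calculator for (resonance) polarizabilities
#' @param asym_tol raise an error when the raw Hessian asymmetry exceeds
#'   this bound (Hartree/Bohr^2); signals a defective calculator
#' @return object of class `derivative_bundle`: symmetrized
#'   `hessian` (3N x 3N, Hartree/Bohr^2), `hessian_raw`, `max_asymmetry`,
#'   `dipole_derivs` (3N x 3, e), `polar_derivs` (3N x 3 x 3 complex,
#'   Bohr^2) or NULL, reference `positions` and `masses` of the active
#'   atoms, `step`, and a per-displacement `provenance` table
#' @export
finite_difference_sweep <- function(calc, struct, rmap = NULL, step = 0.01,
                                    workgroups = 1L, dipole = TRUE,
                                    polarizability = FALSE, omega = 0,
                                    gamma = 0.006, asym_tol = 1e-4) {
  stopifnot(inherits(calc, "calculator"), inherits(struct, "mol_structure"),
            step > 0, workgroups >= 1L)
  if (is.null(rmap))
    rmap <- region_map(n_atoms(struct), inner = seq_len(n_atoms(struct)))
  v <- rmap$vib_active
  N <- length(v)
  ncoord <- 3L * N
  req <- property_request(gradient = TRUE, dipole = dipole,
                          polarizability = polarizability,
                          omega = omega, gamma = gamma)
  # coordinate ci -> (active atom j, axis a), atom-major
  atom_of <- rep(seq_len(N), each = 3L)
  axis_of <- rep(1:3, N)
  grad_idx <- as.integer(3L * (rep(v, each = 3L) - 1L) + rep(1:3, N))

  one_point <- function(ci, sgn) {
    s2 <- struct
    s2$positions[axis_of[ci], v[atom_of[ci]]] <-
      s2$positions[axis_of[ci], v[atom_of[ci]]] + sgn * step
    b <- tryCatch(evaluate(calc, s2, NULL, req), error = function(e)
      stop("single point failed at coordinate ", ci, " (atom ",
           v[atom_of[ci]], ", axis ", c("x", "y", "z")[axis_of[ci]],
           ", sign ", sgn, "): ", conditionMessage(e), call. = FALSE))
    if (!all(is.finite(b$gradient)))
      stop("non-finite gradient at coordinate ", ci, ", sign ", sgn)
    b
  }

  M <- min(as.integer(workgroups), ncoord)
  groups <- split(seq_len(ncoord),
                  rep(seq_len(M), each = ceiling(ncoord / M))[seq_len(ncoord)])
  results <- vector("list", ncoord)
  for (g in groups) {
    for (ci in g) {
      results[[ci]] <- list(plus = one_point(ci, +1),
                            minus = one_point(ci, -1))
    }
  }

  H <- matrix(0, ncoord, ncoord)
  dmu <- if (dipole) matrix(0, ncoord, 3L) else NULL
  dal <- if (polarizability)
    array(0 + 0i, dim = c(ncoord, 3L, 3L)) else NULL
  prov <- data.frame(coord = rep(seq_len(ncoord), each = 2L),
                     atom = rep(v[atom_of], each = 2L),
                     axis = rep(c("x", "y", "z")[axis_of], each = 2L),
                     sign = rep(c(1, -1), ncoord),
                     energy = NA_real_)
  for (ci in seq_len(ncoord)) {
    bp <- results[[ci]]$plus
    bm <- results[[ci]]$minus
    H[, ci] <- (bp$gradient[grad_idx] - bm$gradient[grad_idx]) / (2 * step)
    if (dipole) dmu[ci, ] <- (bp$dipole - bm$dipole) / (2 * step)
    if (polarizability)
      dal[ci, , ] <- (bp$polarizability - bm$polarizability) / (2 * step)
    prov$energy[2L * ci - 1L] <- bp$energy
    prov$energy[2L * ci] <- bm$energy
  }
  asym <- max(abs(H - t(H)))
  if (asym > asym_tol)
    stop("Hessian asymmetry ", format(asym, digits = 4),
         " Hartree/Bohr^2 exceeds tolerance ", asym_tol,
         "; the calculator's gradients are inconsistent")
  structure(list(
    hessian = (H + t(H)) / 2, hessian_raw = H, max_asymmetry = asym,
    dipole_derivs = dmu, polar_derivs = dal, step = step,
    vib_atoms = v, elements = struct$elements[v],
    masses = struct$masses[v],
    positions = struct$positions[, v, drop = FALSE],
    n_active = N,
    provenance = prov),
    class = "derivative_bundle")
}

#' @export
print.derivative_bundle <- function(x, ...) {
  cat("derivative_bundle:", x$n_active, "active atoms |",
      3L * x$n_active, "coordinates | step", x$step, "Bohr\n")
  cat("  max Hessian asymmetry:", format(x$max_asymmetry, digits = 3),
      "Hartree/Bohr^2\n")
  cat("  dipole derivatives:", !is.null(x$dipole_derivs),
      "| polarizability derivatives:", !is.null(x$polar_derivs), "\n")
  invisible(x)
}

# Orthonormal rigid translation/rotation basis in the mass-weighted metric.
# Returns a 3N x k matrix, k = 6 (5 for linear arrangements).
.tr_basis <- function(positions, masses, tol = 1e-8) {
  N <- length(masses)
  w <- rep(sqrt(masses), each = 3L)
  com <- as.numeric(positions %*% masses) / sum(masses)
  rel <- positions - com
  vecs <- matrix(0, 3L * N, 6L)
  for (a in 1:3) {                       # translations
    t <- matrix(0, 3, N); t[a, ] <- 1
    vecs[, a] <- as.numeric(t) * w
  }
  ex <- diag(3)
  for (a in 1:3) {                       # rotations: e_a x (r - com)
    rot <- apply(rel, 2, function(r)
      c(ex[2, a] * r[3] - ex[3, a] * r[2],
        ex[3, a] * r[1] - ex[1, a] * r[3],
        ex[1, a] * r[2] - ex[2, a] * r[1]))
    vecs[, 3 + a] <- as.numeric(rot) * w
  }
  qrd <- qr(vecs, tol = tol)
  qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]
}

#' Normal-mode analysis of a derivative bundle
#'
#' Diagonalizes the mass-weighted Hessian.  Eigenvalues map to signed
#' wavenumbers \eqn{\mathrm{sign}(\lambda)\sqrt{|\lambda|}} (negative
#' encodes imaginary); modes are reported in ascending order, imaginary
#' first.  By default no rigid-body projection is applied: for an embedded
#' active region the nominally translational and rotational motions are
#' genuine vibrations and all 3N modes are kept.  `project_tr = TRUE`
#' switches to free-molecule mode, projecting out 6 (5 for linear) rigid
#' motions before diagonalization.
#'
#' @param bundle a [finite_difference_sweep()] result
#' @param masses optional per-active-atom masses in amu overriding the
#'   masses stored in the bundle (the isotope mechanism)
#' @param project_tr project out rigid translations/rotations?
#' @param zero_threshold reporting threshold in cm^-1 below which a mode is
#'   counted as zero (reporting only; no modes are dropped)
#' @return object of class `mode_set`: `frequencies` (cm^-1, signed),
#'   `modes` (3N x 3N, columns orthonormal in the mass-weighted metric),
#'   `eigenvalues`, `masses`, `n_zero`
#' @export
normal_modes <- function(bundle, masses = NULL, project_tr = FALSE,
                         zero_threshold = 1.0) {
  stopifnot(inherits(bundle, "derivative_bundle"))
  masses <- masses %||% bundle$masses
  if (length(masses) != bundle$n_active)
    stop("expected ", bundle$n_active, " masses, got ", length(masses))
  if (!all(is.finite(bundle$hessian)))
    stop("non-finite Hessian entries")
  w <- rep(1 / sqrt(masses), each = 3L)
  Hmw <- bundle$hessian * outer(w, w)
  if (project_tr) {
    V <- .tr_basis(bundle$positions, masses)
    P <- diag(nrow(Hmw)) - V %*% t(V)
    Hmw <- P %*% Hmw %*% P
    Hmw <- (Hmw + t(Hmw)) / 2
  }
  eig <- eigen(Hmw, symmetric = TRUE)
  lam <- eig$values
  freq <- sign(lam) * sqrt(abs(lam)) * unit_constants()$freq_cm1
  ord <- order(freq)
  lam <- lam[ord]
  freq <- freq[ord]
  L <- eig$vectors[, ord, drop = FALSE]
  # sign convention: largest-magnitude component positive (first on ties)
  for (i in seq_len(ncol(L))) {
    k <- which.max(abs(L[, i]))
    if (L[k, i] < 0) L[, i] <- -L[, i]
  }
  structure(list(frequencies = freq, modes = L, eigenvalues = lam,
                 masses = masses, project_tr = project_tr,
                 zero_threshold = zero_threshold,
                 n_zero = sum(abs(freq) < zero_threshold)),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat("mode_set:", length(x$frequencies), "modes |",
      sum(x$frequencies < -x$zero_threshold), "imaginary |",
      x$n_zero, "below", x$zero_threshold, "cm^-1",
      if (x$project_tr) "| rigid motions projected" else "", "\n")
  cat("  frequencies (cm^-1):",
      paste(format(x$frequencies, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Chain-rule projection of Cartesian property derivatives onto modes
#'
#' \eqn{\partial\mu/\partial Q_i = \sum_k (\partial\mu/\partial x_k)
#' m_k^{-1/2} L_{ki}} and identically for the polarizability.  Units:
#' e/sqrt(amu) for dipole derivatives, Bohr^2/sqrt(amu) for polarizability
#' derivatives.
#'
#' @param bundle a [finite_difference_sweep()] result
#' @param modes a [normal_modes()] result (its masses are used)
#' @return object of class `mode_derivatives`: `dmu_dQ` (3N x 3) and
#'   `dalpha_dQ` (3N x 3 x 3 complex) or NULL
#' @export
project_to_modes <- function(bundle, modes) {
  stopifnot(inherits(bundle, "derivative_bundle"),
            inherits(modes, "mode_set"))
  ncoord <- 3L * bundle$n_active
  if (nrow(modes$modes) != ncoord)
    stop("mode set size does not match bundle (", nrow(modes$modes),
         " vs ", ncoord, ")")
  w <- rep(1 / sqrt(modes$masses), each = 3L)
  dmu_dQ <- NULL
  if (!is.null(bundle$dipole_derivs))
    dmu_dQ <- t(modes$modes) %*% (w * bundle$dipole_derivs)
  dalpha_dQ <- NULL
  if (!is.null(bundle$polar_derivs)) {
    flat <- matrix(bundle$polar_derivs, nrow = ncoord, ncol = 9L)
    proj <- t(modes$modes) %*% (w * flat)
    dalpha_dQ <- array(proj, dim = c(ncoord, 3L, 3L))
  }
  structure(list(dmu_dQ = dmu_dQ, dalpha_dQ = dalpha_dQ),
            class = "mode_derivatives")
}

#' Isotope restart: re-derive modes and mode derivatives with new masses
#'
#' Because the sweep stores plain Cartesian derivatives, an isotope study
#' is a pure post-processing step: amend the atomic masses and recompute —
#' no new single-point calculations are performed.
#'
#' @param bundle a stored [finite_difference_sweep()] result
#' @param new_masses per-active-atom masses in amu
#' @param project_tr passed to [normal_modes()]
#' @return list with `modes` (a `mode_set`) and `mode_derivatives`
#' @export
remass_restart <- function(bundle, new_masses, project_tr = FALSE) {
  stopifnot(inherits(bundle, "derivative_bundle"))
  if (length(new_masses) != bundle$n_active)
    stop("expected ", bundle$n_active, " masses, got ", length(new_masses))
  if (any(!is.finite(new_masses)) || any(new_masses <= 0))
    stop("masses must be positive and finite")
  modes <- normal_modes(bundle, masses = new_masses,
                        project_tr = project_tr)
  list(modes = modes, mode_derivatives = project_to_modes(bundle, modes))
}
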