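# Pluggable property providers.
#
# A calculator is a stateless (w.r.t. geometry) object fulfilling one
# contract: evaluate(calc, structure, external_charges, request) returns a
# property_bundle with the requested fields.  Statelessness is what makes
# task-farmed finite differences deterministic.  Three analytic model
# engines are bundled: a Morse/charge-flux diatomic with bond
# polarizability, a centrosymmetric harmonic A-B-A triatomic, and a
# core-shell ionic engine with Buckingham short-range terms.  Each has
# closed-form derivatives, so they double as oracles for the numerical
# machinery.

#' Property request
#'
#' @param energy,gradient,dipole,polarizability logicals selecting fields
#' @param omega incident radiation frequency in Hartree (0 = static)
#' @param gamma empirical damping for resonance response in Hartree
#'   (default 0.006 a.u., the conventional excited-state lifetime damping)
#' @param field uniform external electric field, 3-vector in a.u.
#' @return object of class `property_request`
#' @export
property_request <- function(energy = TRUE, gradient = FALSE,
                             dipole = FALSE, polarizability = FALSE,
                             omega = 0, gamma = 0.006,
                             field = c(0, 0, 0)) {
  stopifnot(omega >= 0, gamma >= 0, length(field) == 3L)
  structure(list(energy = energy, gradient = gradient, dipole = dipole,
                 polarizability = polarizability, omega = omega,
                 gamma = gamma, field = as.numeric(field)),
            class = "property_request")
}

#' External point charges
#'
#' @param positions 3 x m matrix of charge positions
#' @param charges m charges in e
#' @param units units of positions, "bohr" (default) or "ang"
#' @return object of class `ext_charges`
#' @export
external_charges <- function(positions, charges, units = c("bohr", "ang")) {
  units <- match.arg(units)
  positions <- as.matrix(positions)
  if (nrow(positions) != 3L) stop("positions must be 3 x m")
  if (ncol(positions) != length(charges))
    stop("one charge per position required")
  if (units == "ang") positions <- ang_to_bohr(positions)
  structure(list(positions = unname(positions),
                 charges = as.numeric(charges)),
            class = "ext_charges")
}

.new_calculator <- function(model, params, capabilities) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  structure(list(model = model, params = params,
                 capabilities = capabilities, counter = counter),
            class = c(paste0(model, "_calculator"), "calculator"))
}

#' Properties a calculator can provide
#' @param calc a calculator
#' @return character vector of capability names
#' @export
capabilities <- function(calc) {
  stopifnot(inherits(calc, "calculator"))
  calc$capabilities
}

#' Number of single-point evaluations performed by a calculator
#'
#' Every call to [evaluate()] increments a counter on the calculator.  The
#' isotope-restart path must leave this untouched; tests assert it.
#'
#' @param calc a calculator
#' @return integer call count
#' @export
calculator_calls <- function(calc) {
  stopifnot(inherits(calc, "calculator"))
  calc$counter$n
}

#' Reset a calculator's evaluation counter
#' @param calc a calculator
#' @return invisibly, the calculator
#' @export
reset_calculator_calls <- function(calc) {
  stopifnot(inherits(calc, "calculator"))
  calc$counter$n <- 0L
  invisible(calc)
}

#' @export
print.calculator <- function(x, ...) {
  cat("calculator:", x$model,
      "| capabilities:", paste(x$capabilities, collapse = ", "),
      "| calls:", x$counter$n, "\n")
  invisible(x)
}

#' Evaluate a calculator at a geometry
#'
#' The single entry point of the property-provider contract.  Requested
#' properties are computed at the given geometry; the energy always
#' includes the interaction with any external charges, and gradients on
#' those charges are reported whenever charges are present.  Requesting a
#' property the calculator does not advertise raises a capability error
#' rather than returning silent zeros.
#'
#' @param calc a calculator
#' @param struct a [mol_structure()]
#' @param charges optional [external_charges()]
#' @param request a [property_request()]
#' @return a `property_bundle`: list with `energy` (Hartree), `gradient`
#'   (3N-vector, Hartree/Bohr), `dipole` (3-vector, e Bohr),
#'   `polarizability` (3 x 3 complex, Bohr^3), `ext_charge_gradients`
#'   (3 x m, Hartree/Bohr), plus model-specific extras such as relaxed
#'   shell positions.
#' @export
evaluate <- function(calc, struct, charges = NULL,
                     request = property_request()) {
  stopifnot(inherits(calc, "calculator"), inherits(struct, "mol_structure"),
            inherits(request, "property_request"))
  if (!is.null(charges) && !inherits(charges, "ext_charges"))
    stop("charges must be built with external_charges()")
  wanted <- c("energy", "gradient", "dipole", "polarizability")
  wanted <- wanted[vapply(wanted, function(f) isTRUE(request[[f]]),
                          logical(1))]
  missing_cap <- setdiff(wanted, calc$capabilities)
  if (length(missing_cap))
    stop("calculator '", calc$model, "' cannot provide: ",
         paste(missing_cap, collapse = ", "))
  if (any(request$field != 0) && !("field" %in% calc$capabilities))
    stop("calculator '", calc$model,
         "' does not support a uniform external field")
  calc$counter$n <- calc$counter$n + 1L
  bundle <- eval_model(calc, struct, charges, request)
  class(bundle) <- "property_bundle"
  bundle
}

eval_model <- function(calc, struct, charges, request)
  UseMethod("eval_model")

#' @export
eval_model.default <- function(calc, struct, charges, request)
  stop("no evaluation method for model '", calc$model, "'")

# ---- Coulomb helpers (atomic units: E = q1 q2 / r) -------------------------

# Interaction between two disjoint site sets; returns energy and gradients
# on both sets.
.coulomb_cross <- function(p1, q1, p2, q2) {
  g1 <- matrix(0, 3, ncol(p1))
  g2 <- matrix(0, 3, ncol(p2))
  e <- 0
  for (i in seq_len(ncol(p1))) {
    if (q1[i] == 0) next
    for (j in seq_len(ncol(p2))) {
      if (q2[j] == 0) next
      dv <- p1[, i] - p2[, j]
      d <- sqrt(sum(dv^2))
      e <- e + q1[i] * q2[j] / d
      f <- -q1[i] * q2[j] / d^3 * dv   # dE/dp1 = -q1 q2 (p1-p2)/d^3
      g1[, i] <- g1[, i] + f
      g2[, j] <- g2[, j] - f
    }
  }
  list(energy = e, g1 = g1, g2 = g2)
}

# Coulomb among sites with an owner index; pairs sharing an owner are
# excluded (core and shell of the same atom interact only via the spring).
.coulomb_sites <- function(pos, q, owner) {
  n <- ncol(pos)
  g <- matrix(0, 3, n)
  e <- 0
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (owner[i] == owner[j] || q[i] == 0 || q[j] == 0) next
        dv <- pos[, i] - pos[, j]
        d <- sqrt(sum(dv^2))
        e <- e + q[i] * q[j] / d
        f <- -q[i] * q[j] / d^3 * dv
        g[, i] <- g[, i] + f
        g[, j] <- g[, j] - f
      }
    }
  }
  list(energy = e, g = g)
}

# Damped-Lorentzian frequency dependence of a static polarizability:
# alpha(omega) = alpha_static * we^2 / (we^2 - omega^2 - i Gamma omega).
.lorentz_factor <- function(omega_e, omega, gamma) {
  if (is.null(omega_e)) return(1 + 0i)
  omega_e^2 / (omega_e^2 - omega^2 - 1i * gamma * omega)
}

# ---- Morse / charge-flux diatomic ------------------------------------------

#' Diatomic model calculator (Morse or harmonic, with charge flux and bond
#' polarizability)
#'
#' Potential: Morse \eqn{D(1 - e^{-a(r - r_0)})^2} (harmonic force constant
#' \eqn{k = 2 D a^2}) or pure harmonic \eqn{k (r - r_0)^2 / 2}.  The two
#' atoms carry charges \eqn{\mp q(r)} with the linear charge-flux model
#' \eqn{q(r) = q_0 + q_1 (r - r_0)}, giving dipole
#' \eqn{\mu = q(r) (R_2 - R_1)}.  Bond polarizability:
#' \eqn{\alpha_\parallel = p_0 + p_1 (r - r_0)},
#' \eqn{\alpha_\perp = s_0 + s_1 (r - r_0)}; if `omega_e` is given the
#' static tensor is multiplied by the damped-Lorentzian factor
#' \eqn{\omega_e^2 / (\omega_e^2 - \omega^2 - i\Gamma\omega)}.
#'
#' @param potential "morse" or "harmonic"
#' @param D,a Morse well depth (Hartree) and range (1/Bohr)
#' @param k harmonic force constant (Hartree/Bohr^2)
#' @param r0 equilibrium bond length (Bohr)
#' @param q0,q1 charge-flux parameters (e, e/Bohr)
#' @param alpha_par,alpha_perp length-2 vectors `c(p0, p1)` / `c(s0, s1)`
#'   (Bohr^3, Bohr^2), or NULL for a model with no polarizability terms
#' @param omega_e optional electronic resonance frequency (Hartree)
#' @return a calculator
#' @export
diatomic_calculator <- function(potential = c("morse", "harmonic"),
                                D = NULL, a = NULL, k = NULL, r0,
                                q0 = 0, q1 = 0,
                                alpha_par = NULL, alpha_perp = NULL,
                                omega_e = NULL) {
  potential <- match.arg(potential)
  if (potential == "morse") {
    stopifnot(is.numeric(D), D > 0, is.numeric(a), a > 0)
  } else {
    stopifnot(is.numeric(k), k > 0)
  }
  stopifnot(r0 > 0)
  has_alpha <- !is.null(alpha_par) || !is.null(alpha_perp)
  if (has_alpha) {
    if (is.null(alpha_par)) alpha_par <- c(0, 0)
    if (is.null(alpha_perp)) alpha_perp <- c(0, 0)
    stopifnot(length(alpha_par) == 2L, length(alpha_perp) == 2L)
  }
  caps <- c("energy", "gradient", "dipole", "field")
  if (has_alpha) caps <- c(caps, "polarizability")
  .new_calculator("diatomic",
                  list(potential = potential, D = D, a = a, k = k, r0 = r0,
                       q0 = q0, q1 = q1, alpha_par = alpha_par,
                       alpha_perp = alpha_perp, omega_e = omega_e),
                  caps)
}

#' @export
eval_model.diatomic_calculator <- function(calc, struct, charges, request) {
  p <- calc$params
  if (n_atoms(struct) != 2L)
    stop("diatomic calculator requires exactly 2 atoms")
  R1 <- struct$positions[, 1]
  R2 <- struct$positions[, 2]
  dv <- R2 - R1
  r <- sqrt(sum(dv^2))
  rhat <- dv / r
  dr <- r - p$r0
  if (p$potential == "morse") {
    ex <- exp(-p$a * dr)
    energy <- p$D * (1 - ex)^2
    dVdr <- 2 * p$a * p$D * (1 - ex) * ex
  } else {
    energy <- 0.5 * p$k * dr^2
    dVdr <- p$k * dr
  }
  q <- p$q0 + p$q1 * dr
  qa <- c(-q, q)
  mu <- q * dv
  # gradient on atoms: bond term
  grad <- matrix(0, 3, 2)
  grad[, 1] <- -dVdr * rhat
  grad[, 2] <- dVdr * rhat
  ecg <- NULL
  if (!is.null(charges) && length(charges$charges)) {
    cc <- .coulomb_cross(struct$positions, qa,
                         charges$positions, charges$charges)
    energy <- energy + cc$energy
    grad <- grad + cc$g1
    ecg <- cc$g2
    # charge-flux term: E_ext depends on r through q(r)
    if (p$q1 != 0) {
      phi <- 0
      for (j in seq_along(charges$charges)) {
        phi <- phi +
          charges$charges[j] * (1 / sqrt(sum((R2 - charges$positions[, j])^2)) -
                                1 / sqrt(sum((R1 - charges$positions[, j])^2)))
      }
      grad[, 1] <- grad[, 1] - p$q1 * rhat * phi
      grad[, 2] <- grad[, 2] + p$q1 * rhat * phi
    }
  }
  # uniform field: E -= F . mu with mu = q(r) (R2 - R1)
  F <- request$field
  if (any(F != 0)) {
    energy <- energy - sum(F * mu)
    dmu1 <- -q * diag(3) - p$q1 * outer(dv, rhat)   # [i, j] = d mu_i / d R1_j
    dmu2 <- q * diag(3) + p$q1 * outer(dv, rhat)
    grad[, 1] <- grad[, 1] - as.numeric(t(dmu1) %*% F)
    grad[, 2] <- grad[, 2] - as.numeric(t(dmu2) %*% F)
  }
  alpha <- NULL
  if (isTRUE(request$polarizability)) {
    apar <- p$alpha_par[1] + p$alpha_par[2] * dr
    aperp <- p$alpha_perp[1] + p$alpha_perp[2] * dr
    alpha <- (aperp * diag(3) + (apar - aperp) * outer(rhat, rhat)) *
      .lorentz_factor(p$omega_e, request$omega, request$gamma)
  }
  list(energy = energy, gradient = as.numeric(grad), dipole = mu,
       polarizability = alpha, ext_charge_gradients = ecg)
}

# ---- centrosymmetric A-B-A triatomic ---------------------------------------

#' Centrosymmetric triatomic model calculator (A-B-A)
#'
#' Two harmonic bonds plus a bending term \eqn{k_\theta (1 + \cos\theta)}
#' (smooth at linearity, equal to \eqn{k_\theta (\pi-\theta)^2/2} to
#' quadratic order), fixed atomic charges (neutral by default:
#' \eqn{q_B = -2 q_A}), and an additive bond-polarizability model so that
#' the symmetric stretch is Raman-active/IR-silent and the asymmetric
#' stretch IR-active/Raman-silent — the mutual-exclusion fixture.
#' Atoms must be ordered A, B, A.
#'
#' @param k_bond harmonic bond force constant (Hartree/Bohr^2)
#' @param r0 equilibrium bond length (Bohr)
#' @param k_theta bending stiffness (Hartree)
#' @param q_end charge on each terminal A atom (e)
#' @param q_center charge on the central B atom (default `-2 * q_end`)
#' @param alpha_par,alpha_perp per-bond polarizability parameters
#'   `c(p0, p1)` / `c(s0, s1)`, or NULL
#' @param omega_e optional electronic resonance frequency (Hartree)
#' @return a calculator
#' @export
triatomic_calculator <- function(k_bond, r0, k_theta = 0, q_end = 0,
                                 q_center = -2 * q_end,
                                 alpha_par = NULL, alpha_perp = NULL,
                                 omega_e = NULL) {
  stopifnot(k_bond > 0, r0 > 0, k_theta >= 0)
  has_alpha <- !is.null(alpha_par) || !is.null(alpha_perp)
  if (has_alpha) {
    if (is.null(alpha_par)) alpha_par <- c(0, 0)
    if (is.null(alpha_perp)) alpha_perp <- c(0, 0)
    stopifnot(length(alpha_par) == 2L, length(alpha_perp) == 2L)
  }
  caps <- c("energy", "gradient", "dipole", "field")
  if (has_alpha) caps <- c(caps, "polarizability")
  .new_calculator("triatomic",
                  list(k_bond = k_bond, r0 = r0, k_theta = k_theta,
                       q = c(q_end, q_center, q_end),
                       alpha_par = alpha_par, alpha_perp = alpha_perp,
                       omega_e = omega_e),
                  caps)
}

#' @export
eval_model.triatomic_calculator <- function(calc, struct, charges, request) {
  p <- calc$params
  if (n_atoms(struct) != 3L)
    stop("triatomic calculator requires exactly 3 atoms (ordered A-B-A)")
  R <- struct$positions
  b1 <- R[, 1] - R[, 2]           # B -> A1
  b2 <- R[, 3] - R[, 2]           # B -> A2
  r1 <- sqrt(sum(b1^2)); r2 <- sqrt(sum(b2^2))
  u1 <- b1 / r1; u2 <- b2 / r2
  energy <- 0.5 * p$k_bond * ((r1 - p$r0)^2 + (r2 - p$r0)^2)
  grad <- matrix(0, 3, 3)
  grad[, 1] <- p$k_bond * (r1 - p$r0) * u1
  grad[, 3] <- p$k_bond * (r2 - p$r0) * u2
  grad[, 2] <- -(grad[, 1] + grad[, 3])
  if (p$k_theta > 0) {
    cth <- sum(u1 * u2)
    energy <- energy + p$k_theta * (1 + cth)
    # d cos(theta) / dR: standard angle derivatives, smooth at linearity
    d1 <- (u2 - cth * u1) / r1
    d3 <- (u1 - cth * u2) / r2
    grad[, 1] <- grad[, 1] + p$k_theta * d1
    grad[, 3] <- grad[, 3] + p$k_theta * d3
    grad[, 2] <- grad[, 2] - p$k_theta * (d1 + d3)
  }
  mu <- as.numeric(R %*% p$q)
  ecg <- NULL
  if (!is.null(charges) && length(charges$charges)) {
    cc <- .coulomb_cross(R, p$q, charges$positions, charges$charges)
    energy <- energy + cc$energy
    grad <- grad + cc$g1
    ecg <- cc$g2
  }
  F <- request$field
  if (any(F != 0)) {
    energy <- energy - sum(F * mu)
    for (i in 1:3) grad[, i] <- grad[, i] - p$q[i] * F
  }
  alpha <- NULL
  if (isTRUE(request$polarizability)) {
    bond_alpha <- function(uhat, r) {
      apar <- p$alpha_par[1] + p$alpha_par[2] * (r - p$r0)
      aperp <- p$alpha_perp[1] + p$alpha_perp[2] * (r - p$r0)
      aperp * diag(3) + (apar - aperp) * outer(uhat, uhat)
    }
    alpha <- (bond_alpha(u1, r1) + bond_alpha(u2, r2)) *
      .lorentz_factor(p$omega_e, request$omega, request$gamma)
  }
  list(energy = energy, gradient = as.numeric(grad), dipole = mu,
       polarizability = alpha, ext_charge_gradients = ecg)
}

# ---- core-shell ionic engine -----------------------------------------------

#' Shell-model ionic calculator
#'
#' Polarizable force-field engine for finite ionic clusters.  Atoms take
#' their core charges from the structure's `charges` field; atoms with a
#' `shells` entry carry a massless charged shell bound to the core by a
#' harmonic spring (isolated-ion polarizability \eqn{q_s^2/k}).  Coulomb
#' interactions act between all core/shell sites of distinct atoms;
#' optional Buckingham terms \eqn{A e^{-r/\rho} - C/r^6} act between the
#' shell sites (or cores, for shell-less species) of distinct atoms.
#' Shells are relaxed to equilibrium at every evaluation; the reported
#' dipole and gradients are those of the relaxed configuration
#' (Hellmann-Feynman: at the shell minimum only explicit core-position
#' derivatives survive).
#'
#' @param buckingham optional data.frame with columns `el1, el2, A, rho, C`
#'   (Hartree, Bohr, Hartree Bohr^6)
#' @param shell_tol convergence threshold on the per-cycle shell
#'   displacement change, Bohr (default 1e-7)
#' @param max_iter shell-relaxation iteration cap
#' @return a calculator
#' @export
shell_calculator <- function(buckingham = NULL, shell_tol = 1e-7,
                             max_iter = 500L) {
  if (!is.null(buckingham))
    stopifnot(all(c("el1", "el2", "A", "rho", "C") %in% names(buckingham)))
  .new_calculator("shell",
                  list(buckingham = buckingham, shell_tol = shell_tol,
                       max_iter = as.integer(max_iter)),
                  c("energy", "gradient", "dipole", "field"))
}

.buck_lookup <- function(tbl, e1, e2) {
  if (is.null(tbl)) return(NULL)
  hit <- which((tbl$el1 == e1 & tbl$el2 == e2) |
               (tbl$el1 == e2 & tbl$el2 == e1))
  if (!length(hit)) return(NULL)
  tbl[hit[1], ]
}

# Assemble the site list of a shell-model structure given shell
# displacements d (3 x n_shell).  Sites: all cores, then shells.
.shell_sites <- function(struct, shell_idx, d) {
  n <- n_atoms(struct)
  qs <- vapply(shell_idx, function(i) struct$shells[[i]]$q, numeric(1))
  pos <- cbind(struct$positions,
               struct$positions[, shell_idx, drop = FALSE] + d)
  q <- c(struct$charges, qs)
  owner <- c(seq_len(n), shell_idx)
  list(pos = pos, q = q, owner = owner, qs = qs,
       is_shell = c(rep(FALSE, n), rep(TRUE, length(shell_idx))))
}

# Energy and site gradients of the shell engine at given shell
# displacements (no relaxation).  Returns gradients on cores (3 x n),
# shells (3 x n_shell) and external charges.
.shell_energy_at <- function(calc, struct, charges, field, d) {
  p <- calc$params
  n <- n_atoms(struct)
  shell_idx <- which(!vapply(struct$shells %||% rep(list(NULL), n),
                             is.null, logical(1)))
  st <- .shell_sites(struct, shell_idx, d)
  cs <- .coulomb_sites(st$pos, st$q, st$owner)
  energy <- cs$energy
  gsite <- cs$g
  # springs
  if (length(shell_idx)) {
    ks <- vapply(shell_idx, function(i) struct$shells[[i]]$k, numeric(1))
    energy <- energy + 0.5 * sum(ks * colSums(d^2))
    for (s in seq_along(shell_idx)) {
      f <- ks[s] * d[, s]
      gsite[, n + s] <- gsite[, n + s] + f
      gsite[, shell_idx[s]] <- gsite[, shell_idx[s]] - f
    }
  }
  # Buckingham between repulsion sites (shell if present, else core)
  if (!is.null(p$buckingham) && n >= 2L) {
    rep_site <- seq_len(n)
    rep_site[shell_idx] <- n + seq_along(shell_idx)
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        bp <- .buck_lookup(p$buckingham, struct$elements[i],
                           struct$elements[j])
        if (is.null(bp)) next
        si <- rep_site[i]; sj <- rep_site[j]
        dv <- st$pos[, si] - st$pos[, sj]
        r <- sqrt(sum(dv^2))
        energy <- energy + bp$A * exp(-r / bp$rho) - bp$C / r^6
        dEdr <- -bp$A / bp$rho * exp(-r / bp$rho) + 6 * bp$C / r^7
        f <- dEdr * dv / r
        gsite[, si] <- gsite[, si] + f
        gsite[, sj] <- gsite[, sj] - f
      }
    }
  }
  ecg <- NULL
  if (!is.null(charges) && length(charges$charges)) {
    cc <- .coulomb_cross(st$pos, st$q, charges$positions, charges$charges)
    energy <- energy + cc$energy
    gsite <- gsite + cc$g1
    ecg <- cc$g2
  }
  if (any(field != 0)) {
    # E -= F . sum(q_i r_i) over all sites
    energy <- energy - sum(field * (st$pos %*% st$q))
    gsite <- gsite - outer(field, st$q)
  }
  list(energy = energy,
       g_core = gsite[, seq_len(n), drop = FALSE],
       g_shell = if (length(shell_idx))
         gsite[, n + seq_along(shell_idx), drop = FALSE]
       else matrix(0, 3, 0),
       ext_charge_gradients = ecg,
       shell_idx = shell_idx, sites = st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Spring-preconditioned fixed-point shell relaxation.  The update
# d <- d - f_shell / k has increment equal to the residual force divided by
# the spring constant, so the per-cycle displacement-change criterion is a
# force criterion in disguise.  Deterministic; independent of the starting
# displacements within the quadratic basin.
.shell_relax <- function(calc, struct, charges = NULL, field = c(0, 0, 0),
                         tol = NULL, max_iter = NULL, d0 = NULL) {
  p <- calc$params
  tol <- tol %||% p$shell_tol
  max_iter <- max_iter %||% p$max_iter
  n <- n_atoms(struct)
  shells <- struct$shells %||% rep(list(NULL), n)
  shell_idx <- which(!vapply(shells, is.null, logical(1)))
  if (!length(shell_idx)) {
    ev <- .shell_energy_at(calc, struct, charges, field,
                           matrix(0, 3, 0))
    return(list(displacements = matrix(0, 3, 0), shell_idx = shell_idx,
                energy = ev$energy, iterations = 0L, eval = ev))
  }
  ks <- vapply(shell_idx, function(i) struct$shells[[i]]$k, numeric(1))
  d <- d0 %||% matrix(0, 3, length(shell_idx))
  ev <- NULL
  for (it in seq_len(max_iter)) {
    ev <- .shell_energy_at(calc, struct, charges, field, d)
    step <- sweep(ev$g_shell, 2, ks, "/")
    d <- d - step
    if (max(abs(step)) < tol) {
      ev <- .shell_energy_at(calc, struct, charges, field, d)
      return(list(displacements = d, shell_idx = shell_idx,
                  energy = ev$energy, iterations = it, eval = ev))
    }
  }
  stop("shell relaxation did not converge in ", max_iter,
       " iterations (worst residual displacement change ",
       format(max(abs(sweep(ev$g_shell, 2, ks, "/"))), digits = 3), " Bohr)")
}

#' @export
eval_model.shell_calculator <- function(calc, struct, charges, request) {
  rx <- .shell_relax(calc, struct, charges, request$field)
  ev <- rx$eval
  n <- n_atoms(struct)
  st <- ev$sites
  mu <- as.numeric(st$pos %*% st$q)
  shell_pos <- st$pos[, n + seq_along(rx$shell_idx), drop = FALSE]
  list(energy = ev$energy, gradient = as.numeric(ev$g_core), dipole = mu,
       polarizability = NULL, ext_charge_gradients = ev$ext_charge_gradients,
       shell_positions = shell_pos, shell_idx = rx$shell_idx,
       shell_iterations = rx$iterations)
}

#' Polarizability by finite electric fields
#'
#' Operational polarizability of any calculator that supports a uniform
#' external field: central-difference derivative of the relaxed dipole with
#' respect to the field, \eqn{\alpha_{ij} = \partial\mu_i/\partial F_j}.
#' For a single core-shell ion this equals \eqn{q_s^2/k} exactly; for rigid
#' point-charge models it is zero.
#'
#' @param calc a calculator advertising "dipole" and "field"
#' @param struct a [mol_structure()]
#' @param field_step finite-field step in a.u. (default 1e-3)
#' @return 3 x 3 numeric tensor, Bohr^3
#' @export
finite_field_polarizability <- function(calc, struct, field_step = 1e-3) {
  stopifnot(inherits(calc, "calculator"))
  if (!all(c("dipole", "field") %in% calc$capabilities))
    stop("calculator '", calc$model,
         "' does not support dipole under a uniform field")
  alpha <- matrix(0, 3, 3)
  for (j in 1:3) {
    fp <- fm <- c(0, 0, 0)
    fp[j] <- field_step
    fm[j] <- -field_step
    mup <- evaluate(calc, struct,
                    request = property_request(dipole = TRUE,
                                               field = fp))$dipole
    mum <- evaluate(calc, struct,
                    request = property_request(dipole = TRUE,
                                               field = fm))$dipole
    alpha[, j] <- (mup - mum) / (2 * field_step)
  }
  alpha
}
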