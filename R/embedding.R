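# Additive embedding: compose an inner calculator and a shell-model
# environment engine into one calculator whose energy decomposes as
# E_total = E_inner + E_env + E_coupling.  The inner region sees the
# environment as point charges (cores and, for polarizable embedding,
# relaxed shells); the environment feels the inner region through its
# charge field, and forces on environment atoms include the gradients the
# inner calculator reports on external charges.

#' Embedding options
#'
#' @param scheme "electrostatic" (environment charges rigid) or
#'   "polarizable" (core-shell environment relaxed to mutual
#'   self-consistency with the inner region)
#' @param shell_tol shell-relaxation threshold: max per-cycle shell
#'   displacement change, Bohr
#' @param dipole_tol outer-loop convergence threshold on the change of the
#'   inner dipole between iterations, e Bohr
#' @param max_outer outer (mutual-polarization) iteration cap
#' @return object of class `embedding_options`
#' @export
embedding_options <- function(scheme = c("electrostatic", "polarizable"),
                              shell_tol = 1e-7, dipole_tol = 1e-8,
                              max_outer = 200L) {
  scheme <- match.arg(scheme)
  stopifnot(shell_tol > 0, dipole_tol > 0, max_outer >= 1L)
  structure(list(scheme = scheme, shell_tol = shell_tol,
                 dipole_tol = dipole_tol, max_outer = as.integer(max_outer)),
            class = "embedding_options")
}

# Extract the atoms `idx` of a structure as a new structure.
.subset_structure <- function(struct, idx) {
  sh <- struct$shells
  mol_structure(struct$elements[idx],
                struct$positions[, idx, drop = FALSE], units = "bohr",
                masses = struct$masses[idx], charges = struct$charges[idx],
                shells = if (is.null(sh)) NULL else sh[idx],
                comment = struct$comment)
}

#' Point-charge representation of a calculator's charge distribution
#'
#' How an inner region is presented to the environment shells: its atoms'
#' effective point charges (for the bundled model calculators this is the
#' model's own charge set, including charge flux; for a shell-model inner
#' region, cores plus relaxed shells).
#'
#' @param calc a calculator
#' @param struct the geometry
#' @param bundle optional `property_bundle` from a previous evaluation (used
#'   to reuse relaxed shell positions)
#' @return an [external_charges()] object
#' @export
charge_field <- function(calc, struct, bundle = NULL)
  UseMethod("charge_field")

#' @export
charge_field.diatomic_calculator <- function(calc, struct, bundle = NULL) {
  p <- calc$params
  dv <- struct$positions[, 2] - struct$positions[, 1]
  q <- p$q0 + p$q1 * (sqrt(sum(dv^2)) - p$r0)
  external_charges(struct$positions, c(-q, q))
}

#' @export
charge_field.triatomic_calculator <- function(calc, struct, bundle = NULL) {
  external_charges(struct$positions, calc$params$q)
}

#' @export
charge_field.shell_calculator <- function(calc, struct, bundle = NULL) {
  if (!is.null(bundle) && !is.null(bundle$shell_positions)) {
    sp <- bundle$shell_positions
    sidx <- bundle$shell_idx
  } else {
    rx <- .shell_relax(calc, struct)
    sidx <- rx$shell_idx
    sp <- struct$positions[, sidx, drop = FALSE] + rx$displacements
  }
  qs <- vapply(sidx, function(i) struct$shells[[i]]$q, numeric(1))
  external_charges(cbind(struct$positions, sp),
                   c(struct$charges, qs))
}

#' Relax environment shells in an external field
#'
#' Minimizes the environment energy over shell positions with cores held
#' fixed, under the field of the given external charges and/or a uniform
#' field.  Deterministic spring-preconditioned iteration; the result is
#' independent of the starting shell positions within the quadratic basin.
#'
#' @param env_calc a [shell_calculator()]
#' @param env_struct environment structure (charges and shells on atoms)
#' @param charges optional [external_charges()] acting on the environment
#' @param field optional uniform field, 3-vector a.u.
#' @param tol,max_iter override the engine's relaxation controls
#' @return list with `displacements` (3 x n_shell, Bohr),
#'   `shell_positions`, `shell_idx`, `energy` (relaxed environment energy
#'   including the interaction with the field sources, Hartree),
#'   `induced_dipole` (shell dipole relative to cores, e Bohr),
#'   `iterations`
#' @export
relax_shells <- function(env_calc, env_struct, charges = NULL,
                         field = c(0, 0, 0), tol = NULL, max_iter = NULL) {
  stopifnot(inherits(env_calc, "shell_calculator"))
  rx <- .shell_relax(env_calc, env_struct, charges, field,
                     tol = tol, max_iter = max_iter)
  qs <- vapply(rx$shell_idx, function(i) env_struct$shells[[i]]$q,
               numeric(1))
  mu_ind <- if (length(rx$shell_idx))
    as.numeric(rx$displacements %*% qs) else c(0, 0, 0)
  list(displacements = rx$displacements,
       shell_positions = env_struct$positions[, rx$shell_idx,
                                              drop = FALSE] +
         rx$displacements,
       shell_idx = rx$shell_idx, energy = rx$energy,
       induced_dipole = mu_ind, iterations = rx$iterations)
}

#' Compose an additive embedded calculator
#'
#' Builds a calculator over the full structure whose energy decomposes into
#' inner, environment and coupling parts.  At every evaluation the inner
#' region is evaluated in the field of the environment charges (cores plus
#' shells); for the polarizable scheme, shell relaxation and inner
#' evaluation are alternated until the inner dipole is stationary.
#'
#' @param inner_calc calculator for the inner region
#' @param env_calc a [shell_calculator()] for the environment
#' @param rmap a [region_map()] over the full structure
#' @param options an [embedding_options()]
#' @return a calculator (model "qmmm"); its bundles additionally carry
#'   `components` (E_total, E_inner, E_env, E_coupling), `scf_iterations`
#'   and relaxed `shell_displacements`
#' @export
compose_additive <- function(inner_calc, env_calc, rmap,
                             options = embedding_options()) {
  stopifnot(inherits(inner_calc, "calculator"),
            inherits(env_calc, "shell_calculator"),
            inherits(rmap, "region_map"),
            inherits(options, "embedding_options"))
  caps <- c("energy", "gradient", "dipole")
  if ("polarizability" %in% inner_calc$capabilities)
    caps <- c(caps, "polarizability")
  .new_calculator("qmmm",
                  list(inner = inner_calc, env = env_calc, rmap = rmap,
                       options = options),
                  caps)
}

# Self-consistent (or single-pass electrostatic) evaluation of the
# composite.  Returns the bundle plus iteration diagnostics.
.qmmm_scf <- function(calc, struct, charges, request, state = NULL) {
  p <- calc$params
  rmap <- p$rmap
  opt <- p$options
  if (rmap$n_atoms != n_atoms(struct))
    stop("region map covers ", rmap$n_atoms, " atoms but structure has ",
         n_atoms(struct))
  env_idx <- sort(c(rmap$active_env, rmap$frozen_env))
  inner_struct <- .subset_structure(struct, rmap$inner)
  env_struct <- .subset_structure(struct, env_idx)
  polar <- opt$scheme == "polarizable"
  shells <- env_struct$shells %||% rep(list(NULL), n_atoms(env_struct))
  shell_idx <- which(!vapply(shells, is.null, logical(1)))
  if (polar && !length(shell_idx))
    stop("polarizable embedding requested but the environment has no shells")

  inner_req <- property_request(
    energy = TRUE, gradient = isTRUE(request$gradient), dipole = TRUE,
    polarizability = isTRUE(request$polarizability),
    omega = request$omega, gamma = request$gamma)

  # baseline: isolated inner region
  b_iso <- evaluate(p$inner, inner_struct,
                    request = property_request(energy = TRUE, dipole = TRUE))
  e_inner_iso <- b_iso$energy
  mu_prev <- if (!is.null(state)) state$mu else b_iso$dipole
  inner_field <- if (!is.null(state)) state$inner_field
    else charge_field(p$inner, inner_struct, b_iso)
  d <- if (!is.null(state)) state$d
    else matrix(0, 3, if (polar) length(shell_idx) else 0)

  user_m <- if (is.null(charges)) 0L else length(charges$charges)
  residuals <- numeric(0)
  iterations <- 0L
  b_with <- NULL
  repeat {
    iterations <- iterations + 1L
    # environment shell state under the inner + user field
    field_src <- if (user_m)
      external_charges(cbind(inner_field$positions, charges$positions),
                       c(inner_field$charges, charges$charges))
    else inner_field
    if (polar) {
      rx <- .shell_relax(p$env, env_struct, field_src,
                         tol = opt$shell_tol, d0 = d)
      d <- rx$displacements
    }
    d_used <- if (polar) d else matrix(0, 3, length(shell_idx))
    qs <- vapply(shell_idx, function(i) env_struct$shells[[i]]$q,
                 numeric(1))
    env_sites <- external_charges(
      cbind(env_struct$positions,
            env_struct$positions[, shell_idx, drop = FALSE] + d_used),
      c(env_struct$charges, qs))
    ext_all <- if (user_m)
      external_charges(cbind(env_sites$positions, charges$positions),
                       c(env_sites$charges, charges$charges))
    else env_sites
    b_with <- evaluate(p$inner, inner_struct, ext_all, inner_req)
    mu <- b_with$dipole
    res <- max(abs(mu - mu_prev))
    residuals <- c(residuals, res)
    converged <- res < opt$dipole_tol
    mu_prev <- mu
    if (converged || !polar) break
    if (iterations >= opt$max_outer)
      stop("mutual polarization did not converge in ", opt$max_outer,
           " outer iterations; dipole residual trace: ",
           paste(format(utils::tail(residuals, 5), digits = 3),
                 collapse = ", "))
    inner_field <- charge_field(p$inner, inner_struct, b_with)
  }

  # environment-side energies and gradients at the final shell state
  d_used <- if (polar) d else matrix(0, 3, length(shell_idx))
  ev_mm <- .shell_energy_at(p$env, env_struct, NULL, c(0, 0, 0), d_used)
  field_src <- if (user_m)
    external_charges(cbind(inner_field$positions, charges$positions),
                     c(inner_field$charges, charges$charges))
  else inner_field
  ev_int <- .shell_energy_at(p$env, env_struct, field_src, c(0, 0, 0),
                             d_used)
  e_env <- ev_mm$energy
  # coupling as seen from the inner side (counted once), plus the
  # environment <-> user-charge interaction which the inner side cannot see
  e_env_user <- if (user_m) {
    e_env_inner <- .coulomb_cross(inner_field$positions,
                                  inner_field$charges,
                                  ev_int$sites$pos, ev_int$sites$q)$energy
    ev_int$energy - ev_mm$energy - e_env_inner
  } else 0
  e_coupling <- (b_with$energy - e_inner_iso) + e_env_user
  e_total <- e_inner_iso + e_env + e_coupling

  grad <- NULL
  if (isTRUE(request$gradient)) {
    grad <- matrix(0, 3, n_atoms(struct))
    grad[, rmap$inner] <- matrix(b_with$gradient, 3)
    grad[, env_idx] <- ev_int$g_core
    grad <- as.numeric(grad)
  }
  ecg <- NULL
  if (user_m) {
    n_env_sites <- length(env_sites$charges)
    ecg_inner <- b_with$ext_charge_gradients[, n_env_sites +
                                               seq_len(user_m),
                                             drop = FALSE]
    n_if <- length(inner_field$charges)
    ecg_env <- ev_int$ext_charge_gradients[, n_if + seq_len(user_m),
                                           drop = FALSE]
    ecg <- ecg_inner + ecg_env
  }
  qs <- vapply(shell_idx, function(i) env_struct$shells[[i]]$q, numeric(1))
  env_dipole <- as.numeric(ev_int$sites$pos %*% ev_int$sites$q)
  bundle <- list(
    energy = e_total,
    gradient = grad,
    dipole = b_with$dipole + env_dipole,
    polarizability = b_with$polarizability,
    ext_charge_gradients = ecg,
    components = list(E_total = e_total, E_inner = e_inner_iso,
                      E_env = e_env, E_coupling = e_coupling),
    scf_iterations = iterations,
    shell_displacements = d_used,
    inner_dipole = b_with$dipole)
  state <- list(mu = b_with$dipole, inner_field = inner_field, d = d_used)
  list(bundle = bundle, iterations = iterations, residuals = residuals,
       state = state)
}

#' @export
eval_model.qmmm_calculator <- function(calc, struct, charges, request) {
  .qmmm_scf(calc, struct, charges, request)$bundle
}

#' Run the mutual-polarization loop explicitly
#'
#' Alternates environment shell relaxation (inner charges as field source)
#' and inner evaluation (environment cores and shells as external charges)
#' until the inner dipole changes by less than the configured tolerance.
#' With a non-polarizable inner model or a rigid environment this converges
#' in one outer iteration.
#'
#' @param calc a composite calculator from [compose_additive()]
#' @param struct the full structure
#' @param charges optional additional [external_charges()]
#' @param request a [property_request()]
#' @param state optional warm-start state from a previous call (its
#'   `$state` element); restarting from a converged state converges in one
#'   iteration
#' @return list with `bundle` (self-consistent `property_bundle`),
#'   `components` (energy decomposition), `iterations`, `residuals`
#'   (dipole change per outer iteration, e Bohr) and `state`
#' @export
mutual_polarization <- function(calc, struct, charges = NULL,
                                request = property_request(gradient = TRUE,
                                                           dipole = TRUE),
                                state = NULL) {
  stopifnot(inherits(calc, "qmmm_calculator"))
  calc$counter$n <- calc$counter$n + 1L
  out <- .qmmm_scf(calc, struct, charges, request, state = state)
  class(out$bundle) <- "property_bundle"
  list(bundle = out$bundle, components = out$bundle$components,
       iterations = out$iterations, residuals = out$residuals,
       state = out$state)
}
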