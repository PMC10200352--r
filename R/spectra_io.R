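# Spectrum synthesis and serialization: Lorentzian broadening, peak and
# spectrum tables with deterministic formatting, Molden normal-mode files,
# a JSON restart archive for isotope studies, and the config-driven task
# runner behind the command-line interface.

#' Lorentzian broadening of a stick spectrum
#'
#' Each peak contributes an area-normalized Lorentzian
#' \eqn{I_i \frac{1}{\pi} \frac{\gamma/2}{(\nu - \nu_i)^2 + (\gamma/2)^2}}
#' with full width at half maximum \eqn{\gamma} (peak height
#' \eqn{2 I_i / (\pi\gamma)}).  Broadening is linear in the peak list.
#'
#' @param frequencies peak positions, cm^-1
#' @param intensities peak intensities (same length)
#' @param bandwidth FWHM \eqn{\gamma} in cm^-1 (default 20.0)
#' @param from,to,by uniform grid specification in cm^-1; defaults span the
#'   peaks with a 5-bandwidth margin
#' @return data.frame of class `broadened_spectrum` with columns
#'   `wavenumber`, `intensity`; attribute `bandwidth`
#' @export
broaden_lorentzian <- function(frequencies, intensities, bandwidth = 20,
                               from = NULL, to = NULL, by = 1) {
  stopifnot(bandwidth > 0, by > 0,
            length(frequencies) == length(intensities))
  if (!length(frequencies)) {
    warning("empty peak list: returning an empty spectrum")
    out <- data.frame(wavenumber = numeric(0), intensity = numeric(0))
    attr(out, "bandwidth") <- bandwidth
    class(out) <- c("broadened_spectrum", "data.frame")
    return(out)
  }
  from <- from %||% (min(frequencies) - 5 * bandwidth)
  to <- to %||% (max(frequencies) + 5 * bandwidth)
  grid <- seq(from, to, by = by)
  hw <- bandwidth / 2
  intensity <- numeric(length(grid))
  for (i in seq_along(frequencies)) {
    if (!is.finite(intensities[i])) next
    intensity <- intensity +
      intensities[i] * (hw / pi) / ((grid - frequencies[i])^2 + hw^2)
  }
  out <- data.frame(wavenumber = grid, intensity = intensity)
  attr(out, "bandwidth") <- bandwidth
  class(out) <- c("broadened_spectrum", "data.frame")
  out
}

.fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.10f", x))

#' Write a per-mode peaks table
#'
#' CSV columns: mode index, frequency (cm^-1, signed; negative encodes
#' imaginary), IR intensity (km/mol), unscaled and scaled Raman activity.
#' Formatting is fixed-precision so repeated runs are byte-identical.
#'
#' @param peaks a [spectrum_peaks()] table
#' @param path output path
#' @return invisibly, `path`
#' @export
write_peaks_table <- function(peaks, path) {
  header <- "mode,frequency_cm1,ir_km_mol,raman_unscaled,raman_scaled"
  rows <- if (nrow(peaks))
    sprintf("%d,%s,%s,%s,%s", peaks$mode, .fmt_num(peaks$frequency),
            .fmt_num(peaks$ir_km_mol), .fmt_num(peaks$raman_unscaled),
            .fmt_num(peaks$raman_scaled))
  else character(0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read back a peaks table written by [write_peaks_table()]
#' @param path file path
#' @return data.frame
#' @export
read_peaks_table <- function(path) {
  utils::read.csv(path)
}

#' Write a broadened spectrum as CSV
#' @param spectrum a [broaden_lorentzian()] result
#' @param path output path
#' @return invisibly, `path`
#' @export
write_spectrum_csv <- function(spectrum, path) {
  rows <- if (nrow(spectrum))
    sprintf("%s,%s", .fmt_num(spectrum$wavenumber),
            .fmt_num(spectrum$intensity))
  else character(0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("wavenumber_cm1,intensity", rows), con)
  invisible(path)
}

#' Write a Molden normal-mode file
#'
#' Emits `[Molden Format]` with `[FR-COORD]` (all atoms, Bohr; frozen atoms
#' appear as static coordinates), `[FREQ]` (all 3N mode wavenumbers),
#' `[FR-NORM-COORD]` (Cartesian displacement vectors, obtained from the
#' mass-weighted eigenvectors by dividing by sqrt(m); zero on atoms outside
#' the vibrationally active set) and `[INT]`.
#'
#' @param struct the full structure
#' @param modes a [normal_modes()] result
#' @param peaks a [spectrum_peaks()] table (IR intensities used for
#'   `[INT]` when present, else Raman, else zeros)
#' @param path output path
#' @param rmap region map identifying the vibrationally active atoms;
#'   default: all atoms active
#' @return invisibly, `path`
#' @export
write_molden <- function(struct, modes, peaks, path, rmap = NULL) {
  if (is.null(rmap))
    rmap <- region_map(n_atoms(struct), inner = seq_len(n_atoms(struct)))
  v <- rmap$vib_active
  nmode <- length(modes$frequencies)
  if (nmode != 3L * length(v))
    stop("mode set (", nmode, " modes) does not match ", length(v),
         " vibrationally active atoms")
  lines <- c("[Molden Format]", "[FR-COORD]")
  for (i in seq_len(n_atoms(struct)))
    lines <- c(lines, sprintf("%-3s %16.10f %16.10f %16.10f",
                              struct$elements[i], struct$positions[1, i],
                              struct$positions[2, i],
                              struct$positions[3, i]))
  lines <- c(lines, "[FREQ]", sprintf("%16.10f", modes$frequencies))
  lines <- c(lines, "[FR-NORM-COORD]")
  w <- rep(1 / sqrt(modes$masses), each = 3L)
  for (k in seq_len(nmode)) {
    lines <- c(lines, sprintf("vibration %d", k))
    disp <- matrix(0, 3, n_atoms(struct))
    disp[, v] <- matrix(modes$modes[, k] * w, 3)
    for (i in seq_len(n_atoms(struct)))
      lines <- c(lines, sprintf("%16.10f %16.10f %16.10f",
                                disp[1, i], disp[2, i], disp[3, i]))
  }
  ints <- if (all(is.na(peaks$ir_km_mol))) {
    if (all(is.na(peaks$raman_unscaled))) rep(0, nmode)
    else ifelse(is.na(peaks$raman_unscaled), 0, peaks$raman_unscaled)
  } else ifelse(is.na(peaks$ir_km_mol), 0, peaks$ir_km_mol)
  lines <- c(lines, "[INT]", sprintf("%16.10f", ints))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# ---- restart archive -------------------------------------------------------

#' Save a derivative bundle as a restart archive
#'
#' Versioned JSON schema; numbers are serialized at full IEEE precision so
#' a reload reproduces the sweep bit-exactly.  The archive stores plain
#' Cartesian derivatives, which is what makes isotope restarts possible.
#'
#' @param bundle a [finite_difference_sweep()] result
#' @param path output path (.json)
#' @return invisibly, `path`
#' @export
save_restart <- function(bundle, path) {
  stopifnot(inherits(bundle, "derivative_bundle"))
  obj <- list(
    schema = "qmmvib-restart", version = 1L,
    step = bundle$step, n_active = bundle$n_active,
    vib_atoms = bundle$vib_atoms, elements = bundle$elements,
    masses = bundle$masses,
    positions = as.numeric(bundle$positions),
    hessian_raw = as.numeric(bundle$hessian_raw),
    max_asymmetry = bundle$max_asymmetry,
    dipole_derivs = if (is.null(bundle$dipole_derivs)) NULL
      else as.numeric(bundle$dipole_derivs),
    polar_re = if (is.null(bundle$polar_derivs)) NULL
      else as.numeric(Re(bundle$polar_derivs)),
    polar_im = if (is.null(bundle$polar_derivs)) NULL
      else as.numeric(Im(bundle$polar_derivs)))
  # 17 significant digits: IEEE doubles survive the text round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a restart archive
#' @param path archive path written by [save_restart()]
#' @return a `derivative_bundle`
#' @export
load_restart <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "qmmvib-restart"))
    stop("not a qmmvib restart archive: ", path)
  if (obj$version != 1L)
    stop("unsupported restart archive version ", obj$version)
  N <- as.integer(obj$n_active)
  nc <- 3L * N
  H <- matrix(as.numeric(obj$hessian_raw), nc, nc)
  dal <- NULL
  if (!is.null(obj$polar_re))
    dal <- array(complex(real = as.numeric(obj$polar_re),
                         imaginary = as.numeric(obj$polar_im)),
                 dim = c(nc, 3L, 3L))
  structure(list(
    hessian = (H + t(H)) / 2, hessian_raw = H,
    max_asymmetry = as.numeric(obj$max_asymmetry),
    dipole_derivs = if (is.null(obj$dipole_derivs)) NULL
      else matrix(as.numeric(obj$dipole_derivs), nc, 3L),
    polar_derivs = dal, step = as.numeric(obj$step),
    vib_atoms = as.integer(obj$vib_atoms),
    elements = as.character(obj$elements),
    masses = as.numeric(obj$masses),
    positions = matrix(as.numeric(obj$positions), 3L, N),
    n_active = N, provenance = NULL),
    class = "derivative_bundle")
}

# ---- config-driven task runner ---------------------------------------------

.calculator_from_config <- function(cfg) {
  model <- cfg$model %||% stop("calculator config needs a 'model'")
  params <- cfg$params %||% list()
  switch(model,
    diatomic = do.call(diatomic_calculator, params),
    triatomic = do.call(triatomic_calculator, params),
    shell = {
      if (!is.null(params$buckingham))
        params$buckingham <- as.data.frame(params$buckingham)
      do.call(shell_calculator, params)
    },
    stop("unknown calculator model '", model, "'"))
}

.apply_structure_config <- function(struct, cfg) {
  if (!is.null(cfg$charges)) {
    ch <- as.numeric(cfg$charges)
    if (length(ch) != n_atoms(struct))
      stop("config 'charges' must list one value per atom")
    struct$charges <- ch
  }
  if (!is.null(cfg$shells)) {
    sh <- rep(list(NULL), n_atoms(struct))
    for (s in cfg$shells)
      sh[[as.integer(s$atom)]] <- list(q = as.numeric(s$q),
                                       k = as.numeric(s$k))
    struct$shells <- sh
  }
  struct
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run a configured vibrational-spectroscopy task
#'
#' Executes the full pipeline — finite-difference sweep, normal modes,
#' intensities, broadening — from a YAML config (or an equivalent list) and
#' writes its artifacts to the output directory: `peaks.csv`,
#' `spectrum_ir.csv` / `spectrum_raman.csv` (as enabled), `modes.molden`,
#' `restart.json` and `summary.json`.  The `ir`, `raman` and
#' `resonance_raman` flags toggle which intensities are computed, mirroring
#' the task interface of the underlying method.  All outputs use
#' fixed-precision formatting: identical configs give byte-identical files.
#'
#' Config keys: `structure` (XYZ path), optional `charges` (per atom, e)
#' and `shells` (list of `{atom, q, k}`), `calculator`
#' (`model` + `params`; for embedded runs add `environment`
#' (shell-engine params), `scheme`, and a `regions` block with 1-based
#' `inner` / `active_env` / `frozen_env` / `vib_active`), and `task`
#' (`ir`, `raman`, `resonance_raman`, `omega`, `gamma`, `step`,
#' `workgroups`, `project_tr`, `bandwidth`, `grid: {from, to, by}`).
#'
#' @param config path to a YAML file, or a list with the same shape
#' @param output_dir output directory (default: config `output`, else ".")
#' @return invisibly, a list with the computed `peaks`, `modes`, `bundle`
#'   and the run `summary`
#' @export
run_task <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.character(config) && !is.null(cfg$structure) &&
      !file.exists(cfg$structure)) {
    # resolve the structure path relative to the config file
    cand <- file.path(dirname(config), cfg$structure)
    if (file.exists(cand)) cfg$structure <- cand
  }
  out_dir <- output_dir %||% cfg$output %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  task <- cfg$task %||% list()
  ir <- isTRUE(task$ir %||% TRUE)
  rr <- isTRUE(task$resonance_raman %||% FALSE)
  raman <- isTRUE(task$raman %||% FALSE) || rr
  omega <- if (rr) as.numeric(task$omega %||%
                                stop("resonance_raman needs task.omega"))
    else 0
  gamma <- as.numeric(task$gamma %||% 0.006)
  step <- as.numeric(task$step %||% 0.01)
  wg <- as.integer(task$workgroups %||% 1L)
  bw <- as.numeric(task$bandwidth %||% 20.0)

  struct <- .stage("input", {
    s <- read_xyz(cfg$structure %||% stop("config needs 'structure'"))
    .apply_structure_config(s, cfg)
  })
  rmap <- .stage("regions", {
    rg <- cfg$regions
    if (is.null(rg)) region_map(n_atoms(struct),
                                inner = seq_len(n_atoms(struct)))
    else region_map(n_atoms(struct),
                    inner = as.integer(rg$inner),
                    active_env = as.integer(rg$active_env %||% integer()),
                    frozen_env = as.integer(rg$frozen_env %||% integer()),
                    vib_active = as.integer(rg$vib_active %||% rg$inner))
  })
  calc <- .stage("calculator", {
    inner <- .calculator_from_config(cfg$calculator)
    if (!is.null(cfg$calculator$environment)) {
      env_params <- cfg$calculator$environment
      if (!is.null(env_params$buckingham))
        env_params$buckingham <- as.data.frame(env_params$buckingham)
      env_calc <- do.call(shell_calculator, env_params)
      compose_additive(inner, env_calc, rmap,
                       embedding_options(
                         scheme = cfg$calculator$scheme %||% "electrostatic"))
    } else inner
  })
  bundle <- .stage("sweep",
    finite_difference_sweep(calc, struct, rmap, step = step,
                            workgroups = wg, dipole = TRUE,
                            polarizability = raman, omega = omega,
                            gamma = gamma))
  modes <- .stage("modes",
    normal_modes(bundle, project_tr = isTRUE(task$project_tr)))
  derivs <- .stage("projection", project_to_modes(bundle, modes))
  peaks <- .stage("intensities",
    spectrum_peaks(modes, derivs, ir = ir, raman = raman,
                   omega = omega, gamma = gamma))
  .stage("outputs", {
    write_peaks_table(peaks, file.path(out_dir, "peaks.csv"))
    grid <- task$grid %||% list()
    if (ir) {
      sp <- broaden_lorentzian(peaks$frequency, peaks$ir_km_mol,
                               bandwidth = bw, from = grid$from,
                               to = grid$to, by = grid$by %||% 1)
      write_spectrum_csv(sp, file.path(out_dir, "spectrum_ir.csv"))
    }
    if (raman) {
      sp <- broaden_lorentzian(peaks$frequency, peaks$raman_unscaled,
                               bandwidth = bw, from = grid$from,
                               to = grid$to, by = grid$by %||% 1)
      write_spectrum_csv(sp, file.path(out_dir, "spectrum_raman.csv"))
    }
    write_molden(struct, modes, peaks, file.path(out_dir, "modes.molden"),
                 rmap)
    save_restart(bundle, file.path(out_dir, "restart.json"))
  })
  summary <- list(
    n_atoms = n_atoms(struct), n_active = bundle$n_active,
    step_bohr = step,
    bandwidth_cm1 = bw, ir = ir, raman = raman, resonance_raman = rr,
    omega_hartree = omega, gamma_hartree = gamma,
    project_tr = isTRUE(task$project_tr),
    max_hessian_asymmetry = bundle$max_asymmetry,
    single_points = 6L * bundle$n_active,
    frequencies_cm1 = modes$frequencies)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(peaks = peaks, modes = modes, bundle = bundle,
                 summary = summary))
}

#' Isotope restart from a stored archive
#'
#' Reloads a sweep, amends atomic masses, and recomputes modes and
#' intensities with zero new single-point calculations.
#'
#' @param archive path to a `restart.json` written by [run_task()] or
#'   [save_restart()]
#' @param masses either a full per-active-atom mass vector (amu) or a named
#'   list/vector mapping active-atom indices ("1", "3", ...) to new masses
#' @param output_dir where to write `peaks.csv`; NULL skips writing
#' @param ir,raman which intensities to recompute
#' @param project_tr passed to [normal_modes()]
#' @return invisibly, list with `peaks`, `modes`, `mode_derivatives`
#' @export
restart_task <- function(archive, masses, output_dir = NULL, ir = TRUE,
                         raman = FALSE, project_tr = FALSE) {
  bundle <- load_restart(archive)
  new_masses <- bundle$masses
  if (!is.null(names(masses)) && length(masses) != bundle$n_active) {
    idx <- as.integer(names(masses))
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > bundle$n_active))
      stop("isotope map names must be active-atom indices")
    new_masses[idx] <- as.numeric(masses)
  } else {
    if (length(masses) != bundle$n_active)
      stop("expected ", bundle$n_active, " masses, got ", length(masses))
    new_masses <- as.numeric(masses)
  }
  res <- remass_restart(bundle, new_masses, project_tr = project_tr)
  peaks <- spectrum_peaks(res$modes, res$mode_derivatives, ir = ir,
                          raman = raman && !is.null(bundle$polar_derivs))
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    write_peaks_table(peaks, file.path(output_dir, "peaks.csv"))
  }
  invisible(list(peaks = peaks, modes = res$modes,
                 mode_derivatives = res$mode_derivatives))
}
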