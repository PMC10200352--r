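# A runnable diatomic task config written into a temp dir.
write_diatomic_config <- function(dir, ir = TRUE, raman = FALSE,
                                  resonance_raman = FALSE, omega = 0,
                                  workgroups = 1, bandwidth = 20) {
  xyz <- file.path(dir, "h2.xyz")
  r_ang <- qmmvib::bohr_to_ang(2)
  writeLines(c("2", "model diatomic",
               sprintf("H 0.0 0.0 0.0"),
               sprintf("H 0.0 0.0 %.10f", r_ang)), xyz)
  cfg <- list(
    structure = xyz,
    calculator = list(model = "diatomic",
                      params = list(potential = "harmonic", k = 0.5,
                                    r0 = 2, q0 = 0.3,
                                    alpha_par = c(2, 0.5),
                                    alpha_perp = c(1, 0.2),
                                    omega_e = 0.3)),
    task = list(ir = ir, raman = raman, resonance_raman = resonance_raman,
                omega = omega, step = 0.01, workgroups = workgroups,
                bandwidth = bandwidth,
                grid = list(from = 0, to = 4000, by = 2)))
  path <- file.path(dir, "task.yaml")
  yaml::write_yaml(cfg, path)
  path
}

test_that("Lorentzian broadening has the closed-form height, FWHM and
           area, and is linear in the peak list", {
  sp <- broaden_lorentzian(1000, 1, bandwidth = 20, from = 0, to = 2000,
                           by = 0.5)
  at <- function(nu) sp$intensity[which.min(abs(sp$wavenumber - nu))]
  expect_equal(at(1000), 2 / (20 * pi), tolerance = 1e-10)
  expect_equal(at(1010), at(1000) / 2, tolerance = 1e-10)
  expect_equal(at(990), at(1000) / 2, tolerance = 1e-10)
  # quadrature oracle: trapezoid integral recovers the stick intensity
  area <- sum(diff(sp$wavenumber) *
                (utils::head(sp$intensity, -1) +
                   utils::tail(sp$intensity, -1)) / 2)
  expect_equal(area, 1, tolerance = 0.01)
  # linearity
  a <- broaden_lorentzian(c(800, 1200), c(1, 2), 20, from = 0, to = 2000,
                          by = 1)
  b1 <- broaden_lorentzian(800, 1, 20, from = 0, to = 2000, by = 1)
  b2 <- broaden_lorentzian(1200, 2, 20, from = 0, to = 2000, by = 1)
  expect_equal(a$intensity, b1$intensity + b2$intensity,
               tolerance = 1e-12)
  expect_warning(broaden_lorentzian(numeric(0), numeric(0)), "empty")
})

test_that("peaks tables round-trip and handle edge cases", {
  fx <- fix_triatomic()
  bun <- finite_difference_sweep(fx$calc, fx$struct, polarizability = TRUE)
  modes <- normal_modes(bun)
  peaks <- spectrum_peaks(modes, project_to_modes(bun, modes))
  path <- tempfile(fileext = ".csv")
  write_peaks_table(peaks, path)
  back <- read_peaks_table(path)
  expect_equal(back$frequency_cm1, peaks$frequency, tolerance = 1e-9)
  expect_equal(back$ir_km_mol, peaks$ir_km_mol, tolerance = 1e-9)
  expect_equal(back$raman_unscaled, peaks$raman_unscaled,
               tolerance = 1e-9)
  # negative (imaginary) frequencies keep their sign
  expect_true(any(peaks$frequency < 0) || all(back$frequency_cm1 ==
                                                peaks$frequency))
  empty <- peaks[0, ]
  write_peaks_table(empty, path)
  expect_equal(nrow(read_peaks_table(path)), 0L)
  expect_equal(readLines(path),
               "mode,frequency_cm1,ir_km_mol,raman_unscaled,raman_scaled")
})

test_that("Molden files contain all sections and re-parse to the exact
           frequencies", {
  fx <- fix_triatomic()
  bun <- finite_difference_sweep(fx$calc, fx$struct, polarizability = TRUE)
  modes <- normal_modes(bun)
  peaks <- spectrum_peaks(modes, project_to_modes(bun, modes))
  path <- tempfile(fileext = ".molden")
  write_molden(fx$struct, modes, peaks, path)
  lines <- readLines(path)
  expect_equal(lines[1], "[Molden Format]")
  for (sec in c("[FR-COORD]", "[FREQ]", "[FR-NORM-COORD]", "[INT]"))
    expect_true(sec %in% lines)
  i_freq <- which(lines == "[FREQ]")
  i_nc <- which(lines == "[FR-NORM-COORD]")
  freqs <- as.numeric(lines[(i_freq + 1):(i_nc - 1)])
  expect_length(freqs, 9L)
  expect_equal(freqs, modes$frequencies, tolerance = 1e-9)
})

test_that("restart archives round-trip a sweep bit-exactly", {
  fx <- fix_triatomic()
  bun <- finite_difference_sweep(fx$calc, fx$struct, polarizability = TRUE)
  path <- tempfile(fileext = ".json")
  save_restart(bun, path)
  back <- load_restart(path)
  expect_identical(back$hessian_raw, bun$hessian_raw)
  expect_identical(back$dipole_derivs, bun$dipole_derivs)
  expect_identical(back$polar_derivs, bun$polar_derivs)
  expect_identical(back$masses, bun$masses)
  expect_equal(normal_modes(back)$frequencies,
               normal_modes(bun)$frequencies)
})

test_that("run_task produces the expected artifacts and honors the
           ir/raman flags", {
  dir <- tempfile(); dir.create(dir)
  cfg <- write_diatomic_config(dir, ir = TRUE, raman = FALSE)
  out <- file.path(dir, "out")
  res <- run_task(cfg, out)
  expect_true(all(file.exists(file.path(out,
    c("peaks.csv", "spectrum_ir.csv", "modes.molden", "restart.json",
      "summary.json")))))
  expect_false(file.exists(file.path(out, "spectrum_raman.csv")))
  peaks <- read_peaks_table(file.path(out, "peaks.csv"))
  expect_true(any(peaks$ir_km_mol > 0))
  expect_true(all(is.na(peaks$raman_unscaled)))
  summ <- jsonlite::read_json(file.path(out, "summary.json"),
                              simplifyVector = TRUE)
  expect_false(summ$raman)
  expect_equal(summ$single_points, 12L)
})

test_that("identical configs give byte-identical outputs, for any
           work-group count", {
  dir <- tempfile(); dir.create(dir)
  cfg1 <- write_diatomic_config(dir, raman = TRUE, workgroups = 1)
  out1 <- file.path(dir, "o1"); out2 <- file.path(dir, "o2")
  out5 <- file.path(dir, "o5")
  run_task(cfg1, out1)
  run_task(cfg1, out2)
  cfg5 <- write_diatomic_config(dir, raman = TRUE, workgroups = 5)
  run_task(cfg5, out5)
  for (f in c("peaks.csv", "spectrum_ir.csv", "spectrum_raman.csv",
              "modes.molden", "restart.json")) {
    h1 <- unname(tools::md5sum(file.path(out1, f)))
    expect_identical(unname(tools::md5sum(file.path(out2, f))), h1)
    expect_identical(unname(tools::md5sum(file.path(out5, f))), h1)
  }
})

test_that("resonance runs record omega and gamma and differ from static
           activities", {
  dir <- tempfile(); dir.create(dir)
  cfg_s <- write_diatomic_config(dir, raman = TRUE)
  out_s <- file.path(dir, "static"); run_task(cfg_s, out_s)
  cfg_r <- write_diatomic_config(dir, resonance_raman = TRUE, omega = 0.3)
  out_r <- file.path(dir, "res"); run_task(cfg_r, out_r)
  summ <- jsonlite::read_json(file.path(out_r, "summary.json"),
                              simplifyVector = TRUE)
  expect_true(summ$resonance_raman)
  expect_equal(summ$omega_hartree, 0.3)
  expect_equal(summ$gamma_hartree, 0.006)
  ps <- read_peaks_table(file.path(out_s, "peaks.csv"))
  pr <- read_peaks_table(file.path(out_r, "peaks.csv"))
  stretch_s <- max(ps$raman_unscaled)
  stretch_r <- max(pr$raman_unscaled)
  # model response oracle: on-resonance enhancement (omega_e / Gamma)^2
  expect_equal(stretch_r / stretch_s, (0.3 / 0.006)^2, tolerance = 1e-3)
})

test_that("restart_task amends masses from an archive without new
           evaluations", {
  dir <- tempfile(); dir.create(dir)
  cfg <- write_diatomic_config(dir, raman = TRUE)
  out <- file.path(dir, "out")
  res <- run_task(cfg, out)
  f_h <- max(res$modes$frequencies)
  iso <- restart_task(file.path(out, "restart.json"),
                      masses = c(2.016, 2.016),
                      output_dir = file.path(dir, "iso"), raman = TRUE)
  expect_equal(max(iso$modes$frequencies), f_h / sqrt(2), tolerance = 1e-10)
  expect_true(file.exists(file.path(dir, "iso", "peaks.csv")))
  # partial (named) isotope map
  iso2 <- restart_task(file.path(out, "restart.json"),
                       masses = c("2" = 2.014))
  expect_lt(max(iso2$modes$frequencies), f_h)
})
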