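# Composite fixture: charge-flux diatomic inner region plus a small
# core-shell environment.
fix_embedded <- function(scheme = "electrostatic", env_k = 3,
                         env_qs = -0.8, env_charge = 0.8,
                         with_shells = TRUE, env_z = 6) {
  inner <- diatomic_calculator("harmonic", k = 0.5, r0 = 2, q0 = 0.3,
                               q1 = 0.05)
  env <- shell_calculator()
  pos <- matrix(c(0, 0, 0, 0, 0, 2, 0, 0, env_z), 3)
  shells <- if (with_shells)
    list(NULL, NULL, list(q = env_qs, k = env_k)) else NULL
  struct <- mol_structure(c("H", "H", "O"), pos, units = "bohr",
                          masses = c(1, 1, 16),
                          charges = c(0, 0, env_charge -
                                        if (with_shells) env_qs else 0),
                          shells = shells)
  # net environment charge = env_charge either way
  rmap <- region_map(3, inner = 1:2, frozen_env = 3, vib_active = 1:2)
  calc <- compose_additive(inner, env, rmap, embedding_options(scheme))
  list(calc = calc, struct = struct, inner = inner, env = env,
       rmap = rmap)
}

test_that("composite energy decomposes additively and exactly", {
  fx <- fix_embedded()
  b <- evaluate(fx$calc, fx$struct,
                request = property_request(gradient = TRUE, dipole = TRUE))
  cm <- b$components
  expect_equal(cm$E_total, cm$E_inner + cm$E_env + cm$E_coupling,
               tolerance = 1e-12)
  expect_equal(b$energy, cm$E_total)
})

test_that("a chargeless environment decouples: E_total = E_inner + E_env", {
  fx <- fix_embedded(env_charge = 0, with_shells = FALSE)
  b <- evaluate(fx$calc, fx$struct)
  expect_equal(b$components$E_coupling, 0, tolerance = 1e-14)
})

test_that("inner-environment coupling equals the direct Coulomb sum and the
           force on an environment charge is the analytic Coulomb force", {
  fx <- fix_embedded(with_shells = FALSE, env_charge = 0.8)
  b <- evaluate(fx$calc, fx$struct,
                request = property_request(gradient = TRUE))
  # oracle: inner model charges at r = 2 are (-0.3, +0.3)
  e_oracle <- coulomb_sum(fx$struct$positions[, 1:2, drop = FALSE],
                          c(-0.3, 0.3),
                          fx$struct$positions[, 3, drop = FALSE], 0.8)
  expect_equal(b$components$E_coupling, e_oracle, tolerance = 1e-12)
  # analytic Coulomb force on the environment atom from the inner charges
  f_oracle <- c(0, 0, 0)
  for (i in 1:2) {
    dv <- fx$struct$positions[, 3] - fx$struct$positions[, i]
    d <- sqrt(sum(dv^2))
    f_oracle <- f_oracle + c(-0.3, 0.3)[i] * 0.8 * dv / d^3
  }
  g_env <- matrix(b$gradient, 3)[, 3]
  expect_equal(g_env, -f_oracle, tolerance = 1e-12)
})

test_that("shell relaxation in a uniform field matches the closed form", {
  fx <- fix_shell_atom(qs = 2, k = 4)
  E <- c(0.01, -0.02, 0.015)
  rx <- relax_shells(fx$calc, fx$struct, field = E)
  expect_equal(as.numeric(rx$displacements), 2 * E / 4, tolerance = 1e-9)
  expect_equal(rx$induced_dipole, 2^2 * E / 4, tolerance = 1e-9)
  # zero field: shells stay home
  rx0 <- relax_shells(fx$calc, fx$struct)
  expect_equal(max(abs(rx0$displacements)), 0, tolerance = 1e-12)
  expect_equal(rx0$induced_dipole, c(0, 0, 0), tolerance = 1e-12)
})

test_that("shell relaxation is independent of the starting displacements", {
  fx <- fix_shell_pair()
  ch <- external_charges(matrix(c(0, 1, 3), 3), 0.9)
  a <- relax_shells(fx$calc, fx$struct, ch)
  b <- qmmvib:::.shell_relax(fx$calc, fx$struct, ch,
                             d0 = matrix(0.05, 3, 2))
  expect_equal(a$displacements, b$displacements, tolerance = 1e-6)
})

test_that("polarizable embedding lowers (or keeps) the total energy and the
           rigid-shell limit reduces to electrostatic embedding", {
  fe <- fix_embedded("electrostatic")
  fp <- fix_embedded("polarizable")
  ee <- evaluate(fe$calc, fe$struct)$energy
  ep <- evaluate(fp$calc, fp$struct)$energy
  expect_lte(ep, ee + 1e-14)
  # huge spring constant: shells cannot move, schemes coincide
  fr <- fix_embedded("polarizable", env_k = 1e12)
  fer <- fix_embedded("electrostatic", env_k = 1e12)
  expect_equal(evaluate(fr$calc, fr$struct)$energy,
               evaluate(fer$calc, fer$struct)$energy, tolerance = 1e-10)
})

test_that("polarizable scheme without shells is a configuration error", {
  fx <- fix_embedded("polarizable", with_shells = FALSE)
  expect_error(evaluate(fx$calc, fx$struct), "no shells")
})

test_that("mutual polarization converges in one outer iteration for a
           non-polarizable inner region", {
  fx <- fix_embedded("polarizable")
  mp <- mutual_polarization(fx$calc, fx$struct)
  expect_equal(mp$iterations, 1L)
  expect_lt(mp$residuals[length(mp$residuals)], 1e-8)
})

test_that("mutual polarization fixed point matches brute-force minimization
           of the coupled energy", {
  # polarizable inner (shell ion) + polarizable environment (shell ion):
  # a genuinely mutual problem
  pos <- matrix(c(0, 0, 0, 0, 0, 5), 3)
  struct <- mol_structure(c("O", "O"), pos, units = "bohr",
                          charges = c(1, -1),
                          shells = list(list(q = -1.5, k = 3),
                                        list(q = 1.2, k = 2.5)))
  rmap <- region_map(2, inner = 1, active_env = 2, vib_active = 1)
  calc <- compose_additive(shell_calculator(), shell_calculator(), rmap,
                           embedding_options("polarizable",
                                             dipole_tol = 1e-12,
                                             shell_tol = 1e-12))
  mp <- mutual_polarization(calc, struct)
  expect_gt(mp$iterations, 1L)
  # oracle: joint minimization of the full coupled energy over both shell
  # displacements with optim
  energy_at <- function(d) {
    d <- matrix(d, 3)
    spos <- pos + d
    sites <- cbind(pos, spos)
    q <- c(1, -1, -1.5, 1.2)
    owner <- c(1, 2, 1, 2)
    e <- 0.5 * 3 * sum(d[, 1]^2) + 0.5 * 2.5 * sum(d[, 2]^2)
    for (i in 1:3) for (j in (i + 1):4)
      if (owner[i] != owner[j])
        e <- e + q[i] * q[j] / sqrt(sum((sites[, i] - sites[, j])^2))
    e
  }
  opt <- stats::optim(rep(0, 6), energy_at, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000))
  expect_equal(mp$components$E_total, opt$value, tolerance = 1e-8)

  # self-consistency: restarting from the converged state converges in one
  # iteration
  mp2 <- mutual_polarization(calc, struct, state = mp$state)
  expect_equal(mp2$iterations, 1L)
  expect_equal(mp2$components$E_total, mp$components$E_total,
               tolerance = 1e-12)
})

test_that("composite gradients are consistent with finite differences of
           the composite energy", {
  fx <- fix_embedded("polarizable")
  req <- property_request(gradient = TRUE)
  b <- evaluate(fx$calc, fx$struct, request = req)
  g_num <- fd_gradient(fx$calc, fx$struct, request = req, h = 1e-5)
  expect_lt(max(abs(b$gradient - g_num)), 1e-6)
})
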