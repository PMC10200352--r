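# Fixtures and independent oracles shared across the suite.  All fixtures
# are built in code; geometries are in Bohr unless stated.

# Harmonic or Morse diatomic along z with unit masses by default.
fix_diatomic <- function(potential = "harmonic", k = 0.5, D = 0.1,
                         a = 1.2, r0 = 2, q0 = 0.3, q1 = 0,
                         alpha_par = NULL, alpha_perp = NULL,
                         omega_e = NULL, masses = c(1, 1), r = r0) {
  calc <- diatomic_calculator(potential, D = D, a = a, k = k, r0 = r0,
                              q0 = q0, q1 = q1, alpha_par = alpha_par,
                              alpha_perp = alpha_perp, omega_e = omega_e)
  struct <- mol_structure(c("H", "H"),
                          matrix(c(0, 0, 0, 0, 0, r), 3), units = "bohr",
                          masses = masses)
  list(calc = calc, struct = struct)
}

# Linear centrosymmetric A-B-A along z at its equilibrium geometry.
fix_triatomic <- function(k_bond = 0.5, r0 = 2, k_theta = 0.05,
                          q_end = 0.4, alpha_par = c(2, 0.5),
                          alpha_perp = c(1, 0.2), omega_e = NULL,
                          masses = c(1, 2, 1)) {
  calc <- triatomic_calculator(k_bond = k_bond, r0 = r0,
                               k_theta = k_theta, q_end = q_end,
                               alpha_par = alpha_par,
                               alpha_perp = alpha_perp, omega_e = omega_e)
  struct <- mol_structure(c("H", "He", "H"),
                          matrix(c(0, 0, -r0, 0, 0, 0, 0, 0, r0), 3),
                          units = "bohr", masses = masses)
  list(calc = calc, struct = struct)
}

# One neutral core-shell ion: core +1, shell -1 on a spring.
fix_shell_atom <- function(qs = -1, k = 2, pos = c(0, 0, 0)) {
  struct <- mol_structure("O", matrix(pos, 3), units = "bohr",
                          charges = -qs, shells = list(list(q = qs, k = k)))
  list(calc = shell_calculator(), struct = struct)
}

# Two neutral core-shell ions separated along z.
fix_shell_pair <- function(qs = -1, k = 2, sep = 6) {
  struct <- mol_structure(
    c("O", "O"), matrix(c(0, 0, 0, 0, 0, sep), 3), units = "bohr",
    charges = c(-qs, -qs),
    shells = list(list(q = qs, k = k), list(q = qs, k = k)))
  list(calc = shell_calculator(), struct = struct)
}

# Central-difference numerical gradient of a calculator's energy --
# the independent oracle for every analytic gradient.
fd_gradient <- function(calc, struct, charges = NULL,
                        request = property_request(), h = 1e-5) {
  n <- n_atoms(struct)
  g <- matrix(0, 3, n)
  for (i in seq_len(n)) {
    for (a in 1:3) {
      sp <- sm <- struct
      sp$positions[a, i] <- sp$positions[a, i] + h
      sm$positions[a, i] <- sm$positions[a, i] - h
      ep <- evaluate(calc, sp, charges, request)$energy
      em <- evaluate(calc, sm, charges, request)$energy
      g[a, i] <- (ep - em) / (2 * h)
    }
  }
  as.numeric(g)
}

# Uniformly random proper rotation matrix (QR of a Gaussian matrix).
rand_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Apply a rotation to a structure (positions only; models are covariant).
rotate_structure <- function(struct, R) {
  struct$positions <- R %*% struct$positions
  struct
}

# Direct Coulomb sum oracle: sum over q_i z_j / r_ij in atomic units.
coulomb_sum <- function(pos_a, q_a, pos_b, q_b) {
  e <- 0
  for (i in seq_len(ncol(pos_a)))
    for (j in seq_len(ncol(pos_b)))
      e <- e + q_a[i] * q_b[j] /
        sqrt(sum((pos_a[, i] - pos_b[, j])^2))
  e
}
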