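# Core chemical data model: atoms, structures, region maps, XYZ I/O.
#
# A structure is a column-oriented record (like bio3d's pdb$atom table):
# element symbols, per-atom masses (amu), a 3 x n coordinate matrix in Bohr,
# optional per-atom point charges (e) and optional core-shell attachments.
# Atom order is the index space for all derivative bookkeeping and is never
# reordered by any operation in the package.

# IUPAC 2021 standard atomic weights (conventional values for intervals).
.qmmvib_masses <- c(
  H = 1.008, He = 4.002602, Li = 6.94, Be = 9.0121831, B = 10.81,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998403163, Ne = 20.1797,
  Na = 22.98976928, Mg = 24.305, Al = 26.9815384, Si = 28.085,
  P = 30.973761998, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.0983, Ca = 40.078, Sc = 44.955907, Ti = 47.867, V = 50.9415,
  Cr = 51.9961, Mn = 54.938043, Fe = 55.845, Co = 58.933194,
  Ni = 58.6934, Cu = 63.546, Zn = 65.38, Ga = 69.723, Ge = 72.630,
  As = 74.921595, Se = 78.971, Br = 79.904, Kr = 83.798,
  Rb = 85.4678, Sr = 87.62, Y = 88.905838, Zr = 91.224, Nb = 92.90637,
  Mo = 95.95, Ru = 101.07, Rh = 102.90549, Pd = 106.42, Ag = 107.8682,
  Cd = 112.414, In = 114.818, Sn = 118.710, Sb = 121.760, Te = 127.60,
  I = 126.90447, Xe = 131.293, Cs = 132.90545196, Ba = 137.327,
  W = 183.84, Pt = 195.084, Au = 196.966570, Hg = 200.592,
  Pb = 207.2
)

#' Standard atomic mass of an element
#'
#' Looks up the standard atomic weight, or returns an explicit override
#' (the mechanism behind isotope substitution: amend the masses, keep the
#' force constants).
#'
#' @param element element symbol, e.g. "H"
#' @param override optional mass in amu; returned as-is when supplied
#' @return mass in amu
#' @examples
#' atomic_mass("H")            # 1.008
#' atomic_mass("H", 2.014)     # deuterium
#' @export
atomic_mass <- function(element, override = NULL) {
  if (!is.null(override)) {
    stopifnot(is.numeric(override), override > 0)
    return(as.numeric(override))
  }
  m <- unname(.qmmvib_masses[element])
  if (is.na(m))
    stop("unknown element symbol '", element, "' and no mass override given")
  m
}

#' Build a molecular structure
#'
#' @param elements character vector of element symbols
#' @param positions 3 x n matrix of coordinates (columns are atoms)
#' @param units units of `positions`: "ang" (default) or "bohr"
#' @param masses optional per-atom masses in amu (default: standard weights)
#' @param charges optional per-atom point charges in e (default 0)
#' @param shells optional list, one entry per atom: either NULL or
#'   `list(q = <shell charge e>, k = <spring constant Hartree/Bohr^2>)`
#' @param comment free-text comment carried through XYZ round trips
#' @return object of class `mol_structure` with positions in Bohr
#' @export
mol_structure <- function(elements, positions, units = c("ang", "bohr"),
                          masses = NULL, charges = NULL, shells = NULL,
                          comment = "") {
  units <- match.arg(units)
  positions <- as.matrix(positions)
  if (nrow(positions) != 3L)
    stop("positions must be a 3 x n matrix (columns are atoms)")
  n <- ncol(positions)
  if (n < 1L) stop("a structure needs at least one atom")
  if (length(elements) != n)
    stop("length(elements) != number of atom columns")
  if (!all(is.finite(positions)))
    stop("non-finite coordinates")
  if (units == "ang") positions <- ang_to_bohr(positions)
  if (is.null(masses))
    masses <- vapply(elements, atomic_mass, numeric(1), USE.NAMES = FALSE)
  if (length(masses) != n || any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be ", n, " positive finite values")
  if (is.null(charges)) charges <- numeric(n)
  if (length(charges) != n) stop("charges must have one value per atom")
  if (!is.null(shells)) {
    if (length(shells) != n) stop("shells must have one entry per atom")
    for (s in shells) {
      if (is.null(s)) next
      if (!is.numeric(s$k) || s$k <= 0)
        stop("shell spring constants must be > 0")
    }
  }
  structure(
    list(elements = as.character(elements), masses = as.numeric(masses),
         positions = unname(positions), charges = as.numeric(charges),
         shells = shells, comment = as.character(comment)[1]),
    class = "mol_structure")
}

#' Number of atoms in a structure
#' @param x a `mol_structure`
#' @return integer atom count
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "mol_structure"))
  ncol(x$positions)
}

#' @export
print.mol_structure <- function(x, ...) {
  cat("mol_structure:", n_atoms(x), "atoms\n")
  if (nzchar(x$comment)) cat("  comment:", x$comment, "\n")
  cat("  elements:", paste(x$elements, collapse = " "), "\n")
  invisible(x)
}

#' Read an XYZ file
#'
#' Standard XYZ: atom count, comment line, then `El x y z` with coordinates
#' in Angstrom.  Coordinates are converted to Bohr internally.
#'
#' @param path file path
#' @return a `mol_structure`
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("XYZ parse error at line 1: file too short")
  count <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(count) || count < 1L)
    stop("XYZ parse error at line 1: bad atom count '", lines[1], "'")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != count)
    stop("XYZ parse error: header declares ", count, " atoms but ",
         length(body), " atom lines found")
  elements <- character(count)
  pos <- matrix(NA_real_, 3, count)
  for (i in seq_len(count)) {
    tok <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
    if (length(tok) < 4L)
      stop("XYZ parse error at line ", i + 2L, ": expected 'El x y z'")
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz)))
      stop("XYZ parse error at line ", i + 2L, ": bad coordinate")
    elements[i] <- tok[1]
    pos[, i] <- xyz
  }
  mol_structure(elements, pos, units = "ang", comment = trimws(lines[2]))
}

#' Write an XYZ file
#'
#' @param x a `mol_structure`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_xyz <- function(x, path) {
  stopifnot(inherits(x, "mol_structure"))
  pos <- bohr_to_ang(x$positions)
  lines <- c(
    as.character(n_atoms(x)),
    x$comment,
    vapply(seq_len(n_atoms(x)), function(i)
      sprintf("%-3s %18.12f %18.12f %18.12f", x$elements[i],
              pos[1, i], pos[2, i], pos[3, i]), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Partition atoms into embedding regions
#'
#' `inner`, `active_env` and `frozen_env` must be disjoint and jointly cover
#' all atoms; the vibrationally active subset `vib_active` (the N atoms that
#' are displaced in finite-difference sweeps, giving 3N modes) must lie in
#' `inner` U `active_env`.
#'
#' @param n_atoms total atom count
#' @param inner integer indices (1-based) of the inner (QM-like) region
#' @param active_env indices of the mobile environment
#' @param frozen_env indices of the frozen environment
#' @param vib_active indices of vibrationally active atoms
#'   (default: `inner`)
#' @return object of class `region_map`
#' @export
region_map <- function(n_atoms, inner, active_env = integer(),
                       frozen_env = integer(), vib_active = inner) {
  inner <- sort(unique(as.integer(inner)))
  active_env <- sort(unique(as.integer(active_env)))
  frozen_env <- sort(unique(as.integer(frozen_env)))
  vib_active <- sort(unique(as.integer(vib_active)))
  all_idx <- c(inner, active_env, frozen_env)
  if (anyDuplicated(all_idx))
    stop("inner / active_env / frozen_env must be disjoint")
  if (!setequal(all_idx, seq_len(n_atoms)))
    stop("regions must cover all ", n_atoms, " atoms exactly")
  if (length(vib_active) < 1L)
    stop("vib_active must contain at least one atom")
  if (!all(vib_active %in% c(inner, active_env)))
    stop("vib_active must be a subset of inner + active_env")
  structure(list(inner = inner, active_env = active_env,
                 frozen_env = frozen_env, vib_active = vib_active,
                 n_atoms = as.integer(n_atoms)),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("region_map:", x$n_atoms, "atoms |",
      length(x$inner), "inner,", length(x$active_env), "active env,",
      length(x$frozen_env), "frozen env;",
      length(x$vib_active), "vibrationally active\n")
  invisible(x)
}

#' Mass-weight or un-mass-weight a 3N Cartesian vector
#'
#' Displacement-like quantities transform as \eqn{x \sqrt{m}}; the inverse
#' transform divides by \eqn{\sqrt{m}} (which is also how gradient-like
#' quantities are taken into the mass-weighted metric).
#'
#' @param vec numeric vector of length 3 * length(masses), ordered
#'   (x1, y1, z1, x2, ...)
#' @param masses per-atom masses in amu
#' @param direction "weight" multiplies by sqrt(m); "unweight" divides
#' @return transformed vector
#' @export
mass_weight <- function(vec, masses, direction = c("weight", "unweight")) {
  direction <- match.arg(direction)
  if (length(vec) != 3L * length(masses))
    stop("vector length ", length(vec), " does not match 3 * ",
         length(masses), " mass entries")
  w <- rep(sqrt(masses), each = 3L)
  if (direction == "weight") vec * w else vec / w
}
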