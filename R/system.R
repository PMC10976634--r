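#' @useDynLib vpdft, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm runif
#' @importFrom utils head tail
NULL

# Bohr radius in Angstrom; single source of truth for unit conversion
.bohr <- 0.52917721092
.hartree_ev <- 27.211386
.hartree_kcal <- 627.5095
.au_debye <- 2.541746

.elements <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
               "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
               "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni",
               "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr")

# Bragg-Slater radii (Angstrom) used by the fuzzy-cell partitioning
.bragg <- c(0.35, 0.35, 1.45, 1.05, 0.85, 0.70, 0.65, 0.60, 0.50, 0.50,
            1.80, 1.50, 1.25, 1.10, 1.00, 1.00, 1.00, 1.00,
            2.20, 1.80, 1.60, 1.40, 1.35, 1.40, 1.40, 1.40, 1.35, 1.35,
            1.35, 1.35, 1.30, 1.25, 1.15, 1.15, 1.15, 1.15)

atomic_number <- function(sym) {
  z <- match(sym, .elements)
  if (anyNA(z)) stop("unknown element symbol: ", paste(sym[is.na(z)], collapse = ", "))
  z
}

#' Read an XYZ geometry file
#'
#' Standard two-header-line XYZ dialect with coordinates in Angstrom.
#'
#' @param path path to an .xyz file
#' @return data.frame with columns `element`, `x`, `y`, `z` (Angstrom)
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1]))
  rows <- strsplit(trimws(ln[3:(2 + n)]), "\\s+")
  data.frame(element = vapply(rows, `[[`, "", 1),
             x = as.numeric(vapply(rows, `[[`, "", 2)),
             y = as.numeric(vapply(rows, `[[`, "", 3)),
             z = as.numeric(vapply(rows, `[[`, "", 4)))
}

#' Construct a molecular system
#'
#' Builds the system context: atoms, basis shells, electron count and nuclear
#' repulsion. Coordinates are accepted in Angstrom and stored in Bohr; all
#' energies produced by the package are in Hartree.
#'
#' @param geometry data.frame with columns element, x, y, z (Angstrom), or a
#'   path to an XYZ file
#' @param basis basis-set name (bundled sets: `"sto-3g"`, `"6-31g"`,
#'   `"cc-pvdz"`, `"synthetic-etzv"`) or a basis object from [load_basis()]
#' @param charge total molecular charge
#' @param multiplicity spin multiplicity 2S+1
#' @return an object of class `qc_system`
#' @export
build_system <- function(geometry, basis = "sto-3g", charge = 0L, multiplicity = 1L) {
  if (is.character(geometry)) geometry <- read_xyz(geometry)
  if (nrow(geometry) < 1) stop("empty molecule")
  z <- atomic_number(geometry$element)
  xyz <- as.matrix(geometry[, c("x", "y", "z")]) / .bohr # Bohr internally
  n_el <- sum(z) - charge
  if (n_el < 0) stop("negative electron count")
  if (multiplicity < 1) stop("multiplicity must be >= 1")
  if ((n_el - (multiplicity - 1L)) %% 2L != 0L)
    stop("electron count ", n_el, " incompatible with multiplicity ", multiplicity)
  e_nuc <- 0
  n <- nrow(xyz)
  if (n > 1) {
    for (i in 2:n) for (j in 1:(i - 1)) {
      e_nuc <- e_nuc + z[i] * z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    }
  }
  bs <- if (inherits(basis, "qc_basis")) basis else load_basis(basis)
  shells <- shells_for_molecule(bs, geometry$element, xyz)
  sys <- list(atoms = geometry$element, Z = z, xyz = xyz, charge = charge,
              multiplicity = multiplicity, n_electrons = n_el,
              E_nuc = e_nuc, basis_name = bs$name, shells = shells,
              n_ao = sum(2L * shells$l + 1L))
  class(sys) <- "qc_system"
  sys
}

#' @export
print.qc_system <- function(x, ...) {
  cat("Molecular system:", length(x$atoms), "atoms,",
      x$n_electrons, "electrons, charge", x$charge,
      ", multiplicity", x$multiplicity, "\n")
  cat("Basis:", x$basis_name, "(", x$n_ao, "spherical AOs )\n")
  cat("E_nuc:", format(x$E_nuc, digits = 12), "Ha\n")
  invisible(x)
}

# shell table for a molecule: one row per contracted shell
shells_for_molecule <- function(bs, elements, xyz_bohr) {
  l <- integer(0); cent <- NULL; exps <- list(); coefs <- list(); atom <- integer(0)
  for (i in seq_along(elements)) {
    el <- elements[i]
    blk <- bs$elements[[el]]
    if (is.null(blk)) stop("basis ", bs$name, " has no entry for element ", el)
    for (sh in blk) {
      l <- c(l, sh$l)
      cent <- rbind(cent, xyz_bohr[i, ])
      exps[[length(exps) + 1L]] <- sh$exp
      coefs[[length(coefs) + 1L]] <- sh$coef
      atom <- c(atom, i)
    }
  }
  list(l = l, centers = cent, exps = exps, coefs = coefs, atom = atom)
}

#' Core one-electron integrals
#'
#' Overlap, core Hamiltonian (kinetic + nuclear attraction) and dipole-moment
#' integral matrices over the spherical AO basis.
#'
#' @param sys a `qc_system`
#' @return list with `S`, `T`, `V`, `hcore`, `DX`, `DY`, `DZ`
#' @export
core_integrals <- function(sys) {
  o <- cpp_one_electron(sys$shells$l, sys$shells$centers, sys$shells$exps,
                        sys$shells$coefs, as.numeric(sys$Z), sys$xyz)
  o$hcore <- o$T + o$V
  o
}

#' Two-electron repulsion integrals (packed)
#'
#' Computes the full set of two-electron integrals (mu nu | la si) with
#' eightfold permutational symmetry, stored packed. Schwarz screening is
#' applied at the shell-quartet level.
#'
#' @param sys a `qc_system`
#' @param screen Schwarz screening threshold
#' @return packed numeric vector with attribute `nao`
#' @export
eri_integrals <- function(sys, screen = 1e-12) {
  cpp_eri(sys$shells$l, sys$shells$centers, sys$shells$exps, sys$shells$coefs,
          screen = screen)
}

#' Coulomb matrix J for a density matrix
#'
#' @param eri packed integrals from [eri_integrals()]
#' @param D symmetric AO density matrix (or list of matrices)
#' @param exchange also return the exchange matrix K
#' @return matrix J (or list with J and K; lists of matrices for list input)
#' @export
coulomb_matrix <- function(eri, D, exchange = FALSE) {
  one <- is.matrix(D)
  Ds <- if (one) list(D) else D
  nao <- attr(eri, "nao")
  for (Dm in Ds) {
    if (!is.matrix(Dm) || nrow(Dm) != nao || ncol(Dm) != nao)
      stop("density matrix dimension does not match the integral set")
  }
  r <- cpp_jk(eri, Ds, exchange)
  if (exchange) {
    if (one) list(J = r$J[[1]], K = r$K[[1]]) else r
  } else {
    if (one) r$J[[1]] else r$J
  }
}

# uniform-field perturbation: h' = h + field . r_el (electron charge -1 makes
# E(field) = E0 - mu_total . field); nuclear part handled in energy assembly
field_hcore <- function(ints, field) {
  ints$hcore + field[1] * ints$DX + field[2] * ints$DY + field[3] * ints$DZ
}

nuclear_dipole <- function(sys) as.numeric(crossprod(sys$xyz, sys$Z))
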