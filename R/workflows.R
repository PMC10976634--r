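#' Natural orbital occupation numbers
#'
#' Eigenvalues of the active one-body density matrix, sorted descending;
#' inactive orbitals contribute occupation 2 and are not listed.
#'
#' @param fit an `mcscf` fit
#' @return numeric vector of active-space occupations in [0, 2]
#' @export
natural_occupations <- function(fit) {
  if (fit$actsp$n_orb == 0) return(numeric(0))
  ev <- eigen((fit$rdm$D + t(fit$rdm$D)) / 2, symmetric = TRUE)$values
  sort(pmin(pmax(ev, 0), 2), decreasing = TRUE)
}

#' Dipole moment of a fitted state
#'
#' Expectation value over the total one-body density plus the nuclear term.
#' For variational states this equals the negative derivative of the energy
#' with respect to a uniform electric field (Hellmann-Feynman).
#'
#' @param fit an `mcscf` (or `scf`) fit
#' @param unit `"debye"` (default) or `"au"`
#' @return 3-vector (x, y, z)
#' @export
dipole_moment <- function(fit, unit = c("debye", "au")) {
  unit <- match.arg(unit)
  sys <- fit$sys
  D <- if (inherits(fit, "mcscf")) build_dmats(fit$C, fit$actsp, fit$rdm)$D_total
       else fit$D
  ints <- fit$ints
  mu_el <- -c(sum(D * ints$DX), sum(D * ints$DY), sum(D * ints$DZ))
  mu <- mu_el + nuclear_dipole(sys)
  if (unit == "debye") mu * .au_debye else mu
}

#' Run a single-point calculation from a configuration list
#'
#' @param config list (or path to a YAML file) with keys: `geometry` (XYZ
#'   path or data.frame), `basis`, `charge`, `multiplicity`, `cas` =
#'   c(n_el, n_orb), `method` ("casscf"/"vpdft"/"ppdft"), `functional`,
#'   `grid_level`, `active_orbital_indices` (optional), `conv_grad`
#' @return the `mcscf` fit
#' @export
run_single_point <- function(config) {
  cf <- normalize_config(config)
  sys <- build_system(cf$geometry, cf$basis, cf$charge, cf$multiplicity)
  mcscf(sys, cas = cf$cas, method = cf$method, functional = cf$functional,
        active_orbitals = cf$active_orbital_indices,
        grid_level = cf$grid_level, conv_grad = cf$conv_grad,
        verbose = isTRUE(cf$verbose))
}

normalize_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(charge = 0L, multiplicity = 1L, method = "casscf",
                   functional = NULL, grid_level = 3L, conv_grad = 1e-5,
                   active_orbital_indices = NULL)
  cf <- modifyList(defaults, config)
  if (!cf$method %in% c("casscf", "vpdft", "ppdft"))
    stop("unknown method: ", cf$method)
  if (is.character(cf$geometry) && !file.exists(cf$geometry))
    stop("geometry file not found: ", cf$geometry)
  cf$cas <- as.integer(cf$cas)
  cf
}

#' Dissociation-curve scan of a homonuclear diatomic
#'
#' Runs a warm-started sequence of fits along a list of bond distances and
#' extracts the dissociation energy `D_e = E(last point) - E(minimum)` with a
#' local cubic interpolation of the minimum, and the equilibrium distance
#' `r_e`. The last (largest) distance serves as the asymptote.
#'
#' @param element element symbol of the two atoms
#' @param distances bond lengths in Angstrom (ascending; the last one is the
#'   asymptote)
#' @param basis basis name or object
#' @param cas active space c(n_el, n_orb)
#' @param method,functional as in [mcscf()]
#' @param active_orbitals optional active MO indices for the first point
#' @param grid_level quadrature level for PDFT methods
#' @param conv_grad orbital gradient threshold
#' @param verbose trace
#' @return `scan_result` object with energies, D_e (eV) and r_e (Angstrom)
#' @export
dissociation_scan <- function(element, distances, basis, cas,
                              method = "casscf", functional = NULL,
                              active_orbitals = NULL, grid_level = 3L,
                              conv_grad = 1e-5, verbose = FALSE, ms2 = 0L) {
  if (is.unsorted(distances)) stop("distances must be ascending")
  energies <- rep(NA_real_, length(distances))
  extra <- list()
  C_prev <- NULL; ci_prev <- NULL
  # scan from the largest distance down: the dissociated state is the easy
  # one to converge and warm-starting tracks the same branch inward
  d_prev <- NA_real_
  for (k in rev(seq_along(distances))) {
    d <- distances[k]
    geom <- data.frame(element = c(element, element), x = 0, y = 0, z = c(0, d))
    sys <- build_system(geom, basis)
    # orbitals do not transfer across large geometry jumps (asymptote gap)
    if (!is.na(d_prev) && d_prev - d > 1.5) { C_prev <- NULL; ci_prev <- NULL }
    if (is.null(C_prev) && method %in% c("vpdft", "ppdft")) {
      # cold PDFT points start from the CASSCF solution of the same geometry
      pre <- mcscf(sys, cas = cas, method = "casscf",
                   active_orbitals = active_orbitals,
                   conv_grad = max(conv_grad, 1e-4), ms2 = ms2,
                   max_macro = 60L, on_max_macro = "accept")
      C_prev <- pre$C; ci_prev <- pre$ci
    }
    fit <- mcscf(sys, cas = cas, method = method, functional = functional,
                 active_orbitals = if (is.null(C_prev)) active_orbitals else NULL,
                 C0 = C_prev, ci0 = ci_prev, grid_level = grid_level,
                 conv_grad = conv_grad, ms2 = ms2, max_macro = 80L,
                 trust = if (is.null(C_prev)) 0.3 else 0.1,
                 on_max_macro = "accept", verbose = verbose)
    d_prev <- d
    energies[k] <- fit$E
    C_prev <- fit$C; ci_prev <- fit$ci
    extra[[k]] <- list(E = fit$E, n_macro = fit$n_macro)
    if (verbose) message(sprintf("scan %s d=%.3f A  E=%.8f", element, d, fit$E))
  }
  scan_extract(distances, energies, method, functional,
               meta = list(element = element, basis = if (is.character(basis)) basis else basis$name,
                           cas = cas, grid_level = grid_level))
}

scan_extract <- function(distances, energies, method, functional, meta) {
  n <- length(distances)
  imin <- which.min(energies)
  E_asym <- energies[n]
  out <- list(distances = distances, energies = energies, method = method,
              functional = functional, meta = meta, E_asymptote = E_asym)
  if (imin == n || imin == 1 || energies[imin] >= E_asym) {
    out$D_e <- NA_real_ # repulsive curve: no bound minimum
    out$r_e <- NA_real_
  } else {
    # local cubic fit through up to 5 points around the grid minimum; the
    # asymptote (last point) never enters the fit
    sel <- max(1, imin - 2):min(n - 1L, imin + 2)
    deg <- min(3, length(sel) - 1)
    X <- outer(distances[sel], 0:deg, "^")
    cf <- qr.solve(X, energies[sel])
    xs <- seq(distances[max(1, imin - 1)], distances[min(n - 1L, imin + 1)],
              length.out = 2001)
    ys <- outer(xs, 0:deg, "^") %*% cf
    j <- which.min(ys)
    out$r_e <- xs[j]
    out$E_min <- ys[j]
    out$D_e <- (E_asym - ys[j]) * .hartree_ev
  }
  class(out) <- "scan_result"
  out
}

#' @export
print.scan_result <- function(x, ...) {
  lab <- if (is.null(x$functional)) x$method else paste0(x$method, "-", x$functional)
  cat("Dissociation scan (", x$meta$element, "2, ", lab, ", ", x$meta$basis, ")\n", sep = "")
  for (i in seq_along(x$distances))
    cat(sprintf("  %7.3f A  %16.8f Ha\n", x$distances[i], x$energies[i]))
  if (is.na(x$D_e)) cat("no bound minimum on the scanned range\n")
  else cat(sprintf("D_e = %.4f eV at r_e = %.3f A (asymptote %.8f Ha)\n",
                   x$D_e, x$r_e, x$E_asymptote))
  invisible(x)
}

#' Active-space ladder
#'
#' Energies for a nested sequence of active spaces, for CASSCF and (if a
#' functional is given) variational MC-PDFT; differences against the first
#' entry are reported in kcal/mol.
#'
#' @param sys a `qc_system`
#' @param cas_list list of c(n_el, n_orb), usually nested and growing
#' @param functional optional translated functional for the vpdft column
#' @param grid_level quadrature level
#' @param conv_grad orbital gradient threshold
#' @param verbose trace
#' @return data.frame with energies and lowerings in kcal/mol
#' @export
active_space_ladder <- function(sys, cas_list, functional = NULL,
                                grid_level = 3L, conv_grad = 1e-5,
                                verbose = FALSE) {
  nested <- all(vapply(seq_along(cas_list)[-1], function(i) {
    all(cas_list[[i]] >= cas_list[[i - 1]])
  }, TRUE))
  if (!nested) warning("active-space list is not nested; computing anyway")
  rows <- lapply(cas_list, function(cas) {
    fit_c <- mcscf(sys, cas = cas, method = "casscf", conv_grad = conv_grad,
                   verbose = verbose)
    row <- data.frame(n_el = cas[1], n_orb = cas[2], E_casscf = fit_c$E)
    if (!is.null(functional)) {
      fit_v <- mcscf(sys, cas = cas, method = "vpdft", functional = functional,
                     grid_level = grid_level, conv_grad = conv_grad,
                     verbose = verbose)
      row$E_vpdft <- fit_v$E
    }
    row
  })
  out <- do.call(rbind, rows)
  out$lowering_casscf_kcal <- (out$E_casscf - out$E_casscf[1]) * .hartree_kcal
  if (!is.null(functional))
    out$lowering_vpdft_kcal <- (out$E_vpdft - out$E_vpdft[1]) * .hartree_kcal
  attr(out, "functional") <- functional
  out
}

#' Singlet-triplet gap at fixed geometry
#'
#' Two single-point fits in different M_s sectors; gap in kcal/mol
#' (E_triplet - E_singlet).
#'
#' @param sys a `qc_system` (multiplicity field is overridden per state)
#' @inheritParams mcscf
#' @return list with both fits and the gap
#' @export
singlet_triplet_gap <- function(sys, cas, method = "vpdft", functional = NULL,
                                grid_level = 3L, ...) {
  s_sys <- sys; s_sys$multiplicity <- 1L
  t_sys <- sys; t_sys$multiplicity <- 3L
  fs <- mcscf(s_sys, cas, method = method, functional = functional,
              grid_level = grid_level, ms2 = 0L, ...)
  ft <- mcscf(t_sys, cas, method = method, functional = functional,
              grid_level = grid_level, ms2 = 2L, ...)
  list(singlet = fs, triplet = ft,
       gap_kcal = (ft$E - fs$E) * .hartree_kcal)
}

#' Select pi-system active orbitals of a planar molecule
#'
#' Identifies MOs dominated by AOs that are antisymmetric under reflection in
#' the molecular plane (the pi system) and returns the indices of the
#' `n_el/2` highest such occupied MOs and enough lowest pi virtuals to reach
#' `n_orb` orbitals.
#'
#' @param sys a `qc_system` whose atoms lie in the z = 0 plane
#' @param scf a converged `scf` fit providing orbitals and energies
#' @param n_el,n_orb active-space size
#' @return integer vector of MO indices (in `scf$C` column order)
#' @export
pi_active_indices <- function(sys, scf, n_el, n_orb) {
  if (max(abs(sys$xyz[, 3])) > 1e-6)
    stop("pi selection expects the molecule in the z = 0 plane")
  # z-parity of each spherical AO from its solid-harmonic content
  odd_m <- list(`0` = logical(1), `1` = c(FALSE, TRUE, FALSE),
                `2` = c(FALSE, TRUE, FALSE, TRUE, FALSE),
                `3` = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  # p: (y, z, x); d: (xy, yz, 3z2-r2, xz, x2-y2); f alternating likewise
  odd <- unlist(lapply(sys$shells$l, function(l) odd_m[[as.character(l)]]))
  S <- core_integrals(sys)$S
  wt <- function(mo) {
    c2 <- (S %*% mo) * mo
    sum(c2[odd]) / sum(c2)
  }
  frac <- apply(scf$C, 2, wt)
  nocc <- scf$nocc
  occ_pi <- which(frac[seq_len(nocc)] > 0.5)
  vir_pi <- nocc + which(frac[(nocc + 1):ncol(scf$C)] > 0.5)
  n_occ_need <- n_el %/% 2L
  if (length(occ_pi) < n_occ_need || length(vir_pi) < n_orb - n_occ_need)
    stop("could not identify enough pi orbitals")
  c(tail(occ_pi, n_occ_need), head(vir_pi, n_orb - n_occ_need))
}

#' Standard planar geometry of benzene
#' @param r_cc,r_ch bond lengths in Angstrom
#' @return geometry data.frame (molecule in the z = 0 plane)
#' @export
benzene_geometry <- function(r_cc = 1.397, r_ch = 1.084) {
  th <- (0:5) * pi / 3
  data.frame(element = rep(c("C", "H"), each = 6),
             x = c(r_cc * cos(th), (r_cc + r_ch) * cos(th)),
             y = c(r_cc * sin(th), (r_cc + r_ch) * sin(th)),
             z = 0)
}
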