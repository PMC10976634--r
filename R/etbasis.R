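# Synthetic atom-optimised even-tempered basis sets.
#
# For elements whose published triple-zeta parameters are not bundled, the
# package can construct a synthetic substitute: an even-tempered primitive
# ladder per angular channel, generally contracted with the atomic SCF
# orbitals of the neutral atom (ANO-style), with the outermost primitives
# left free and rule-based polarization shells. The result is written in the
# same plain-text basis format as the bundled sets.

.et_recipes <- list(
  Mg = list(mult = 1L,
            s = list(emin = 0.025, ratio = 2.70, n = 16, n_free = 3, n_core = 3),
            p = list(emin = 0.050, ratio = 2.70, n = 11, n_free = 4, n_core = 1),
            pol = list(list(l = 2L, exp = 0.35), list(l = 2L, exp = 0.11))),
  Cu = list(mult = 2L,
            s = list(emin = 0.032, ratio = 2.75, n = 16, n_free = 3, n_core = 4),
            p = list(emin = 0.065, ratio = 2.70, n = 11, n_free = 2, n_core = 2),
            d = list(emin = 0.095, ratio = 3.00, n = 8, n_free = 3, n_core = 1),
            pol = list(list(l = 3L, exp = 1.50)))
)

#' Generate a synthetic even-tempered, atomically contracted basis
#'
#' Runs an unrestricted atomic SCF in an uncontracted even-tempered primitive
#' set and contracts each angular channel with the resulting atomic orbitals;
#' the outermost primitives stay uncontracted and polarization shells are
#' added by rule. This is a stand-in constructed by the package itself, not a
#' published basis set.
#'
#' @param element element symbol (recipes bundled for Mg and Cu)
#' @return a `qc_basis` object for the single element
#' @export
generate_et_basis <- function(element) {
  rec <- .et_recipes[[element]]
  if (is.null(rec)) stop("no even-tempered recipe for element ", element)
  chans <- intersect(names(rec), c("s", "p", "d"))
  lmap <- c(s = 0L, p = 1L, d = 2L)
  # uncontracted atomic calculation
  sh <- list(l = integer(0), centers = NULL, exps = list(), coefs = list(), atom = integer(0))
  chan_exps <- list()
  for (ch in chans) {
    r <- rec[[ch]]
    ex <- r$emin * r$ratio^(seq_len(r$n) - 1)
    chan_exps[[ch]] <- ex
    for (e in ex) {
      sh$l <- c(sh$l, lmap[[ch]])
      sh$centers <- rbind(sh$centers, c(0, 0, 0))
      sh$exps[[length(sh$exps) + 1L]] <- e
      sh$coefs[[length(sh$coefs) + 1L]] <- 1.0
      sh$atom <- c(sh$atom, 1L)
    }
  }
  z <- atomic_number(element)
  sys <- list(atoms = element, Z = z, xyz = matrix(0, 1, 3), charge = 0L,
              multiplicity = rec$mult, n_electrons = z, E_nuc = 0,
              basis_name = "et-uncontracted", shells = sh,
              n_ao = sum(2L * sh$l + 1L))
  class(sys) <- "qc_system"
  C0 <- NULL
  if (rec$mult > 1L) {
    # warm start from the closed-shell cation, which converges easily
    cat_sys <- sys
    cat_sys$charge <- 1L
    cat_sys$n_electrons <- z - 1L
    cat_sys$multiplicity <- 1L
    C0 <- tryCatch(scf_rhf(cat_sys, level_shift = 0.5, max_iter = 300L)$C,
                   error = function(e) NULL)
  }
  fit <- scf_uhf(sys, conv_grad = 1e-6, level_shift = 0.5, C0 = C0,
                 max_iter = 500L)
  # channel-resolved contraction vectors from the alpha orbitals
  shells_out <- list()
  ao_l <- rep(sh$l, times = 2L * sh$l + 1L)
  # map: for channel ch, the AO rows of each primitive's m-components
  for (ch in chans) {
    r <- rec[[ch]]
    lv <- lmap[[ch]]
    ex <- chan_exps[[ch]]
    # AO rows per primitive shell of this l, one column per m-component
    rows <- NULL
    off <- 0L
    for (k in seq_along(sh$l)) {
      if (sh$l[k] == lv) rows <- rbind(rows, off + seq_len(2L * lv + 1L))
      off <- off + 2L * sh$l[k] + 1L
    }
    # atomic MOs dominated by this channel, one per degenerate group
    Ca <- fit$Ca
    frac <- colSums(Ca[ao_l == lv, , drop = FALSE]^2) / colSums(Ca^2)
    cand <- which(frac > 0.8)
    if (length(cand)) {
      # drop m-degenerate duplicates: keep first of each near-degenerate set
      keep <- cand[1]
      for (mo in cand[-1]) {
        keep_mo <- TRUE
        for (km in keep) {
          # same-energy partners differ only in m; compare channel profiles
          pk <- profile_of(Ca, rows, km)
          pm <- profile_of(Ca, rows, mo)
          if (abs(abs(sum(pk * pm)) / sqrt(sum(pk^2) * sum(pm^2))) > 0.99) {
            keep_mo <- FALSE
            break
          }
        }
        if (keep_mo) keep <- c(keep, mo)
      }
      cand <- keep
    }
    cand <- cand[seq_len(min(length(cand), r$n_core))]
    for (mo in cand) {
      cf <- profile_of(Ca, rows, mo)
      cf <- cf / cf[which.max(abs(cf))]
      shells_out[[length(shells_out) + 1L]] <- list(l = lv, exp = ex, coef = cf)
    }
    nf <- r$n_free
    for (e in ex[seq_len(nf)])
      shells_out[[length(shells_out) + 1L]] <- list(l = lv, exp = e, coef = 1.0)
  }
  for (p in rec$pol)
    shells_out[[length(shells_out) + 1L]] <- list(l = p$l, exp = p$exp, coef = 1.0)
  out <- list()
  out[[element]] <- shells_out
  structure(list(name = "synthetic-etzv", elements = out), class = "qc_basis")
}

# radial profile of one MO in a channel: coefficients on the dominant
# m-component of each primitive shell
profile_of <- function(Ca, rows, mo) {
  nm <- ncol(rows)
  w <- vapply(seq_len(nm), function(m) sum(Ca[rows[, m], mo]^2), 0)
  Ca[rows[, which.max(w)], mo]
}

#' Write a basis object to the plain-text basis format
#'
#' @param bs a `qc_basis`
#' @param path output file
#' @param header comment line(s) written at the top
#' @export
write_basis <- function(bs, path, header = NULL) {
  ln <- c(if (!is.null(header)) paste("#", header))
  lrev <- c("S", "P", "D", "F")
  for (el in names(bs$elements)) {
    ln <- c(ln, el)
    for (shl in bs$elements[[el]]) {
      ln <- c(ln, lrev[shl$l + 1L])
      for (k in seq_along(shl$exp))
        ln <- c(ln, sprintf("%.8f %.10f", shl$exp[k], shl$coef[k]))
    }
    ln <- c(ln, "*")
  }
  writeLines(ln, path)
  invisible(path)
}

#' Merge basis objects
#' @param ... `qc_basis` objects
#' @param name name of the merged set
#' @return a `qc_basis` covering the union of elements
#' @export
merge_basis <- function(..., name = "merged") {
  els <- list()
  for (b in list(...)) els[names(b$elements)] <- b$elements
  structure(list(name = name, elements = els), class = "qc_basis")
}
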