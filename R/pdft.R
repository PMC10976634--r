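#' Active-space definition
#'
#' @param sys a `qc_system`
#' @param n_el number of active electrons
#' @param n_orb number of active orbitals
#' @param ms2 twice the spin projection; defaults to the high-spin value for
#'   the system multiplicity
#' @return an `active_space` object with inactive/active/virtual index ranges
#' @export
active_space <- function(sys, n_el, n_orb, ms2 = sys$multiplicity - 1L) {
  n_inact <- (sys$n_electrons - n_el) / 2
  if (n_inact != round(n_inact) || n_inact < 0)
    stop("active electron count incompatible with total electron count")
  if (n_el < 0 || n_el > 2 * n_orb) stop("impossible active space")
  structure(list(n_el = as.integer(n_el), n_orb = as.integer(n_orb),
                 n_inactive = as.integer(n_inact), ms2 = as.integer(ms2),
                 inactive = seq_len(n_inact),
                 active = n_inact + seq_len(n_orb)),
            class = "active_space")
}

#' Nonseparable part of the active 2-RDM
#'
#' Removes the single-determinant (separable) part from the spin-summed
#' active 2-RDM: `G^ns_tuvw = G_tuvw - D_tu D_vw + 1/2 D_tw D_uv`. It vanishes
#' identically for a closed-shell single determinant and depends on no
#' inactive quantity.
#'
#' @param G active 2-RDM (A^4 array, project convention)
#' @param D active 1-RDM (A x A)
#' @return array of the same shape
#' @export
nonseparable_2dm <- function(G, D) {
  A <- nrow(D)
  if (A == 0) return(array(0, c(0, 0, 0, 0)))
  tr <- sum(diag(D))
  # trace over the second electron: sum_v Gamma_tuvv = (N - 1) D_tu
  pt <- matrix(0, A, A)
  for (t in seq_len(A)) for (u in seq_len(A))
    pt[t, u] <- sum(vapply(seq_len(A), function(v) G[t, u, v, v], 0))
  if (max(abs(pt - (tr - 1) * D)) > 1e-8 * max(1, abs(tr)))
    stop("2-RDM partial trace inconsistent with the 1-RDM")
  sep <- outer(D, D) - 0.5 * aperm(outer(D, D), c(1, 4, 3, 2))
  G - sep
}

# density matrices for a wave function state
build_dmats <- function(C, actsp, rdm) {
  Cin <- C[, actsp$inactive, drop = FALSE]
  Cact <- C[, actsp$active, drop = FALSE]
  D_in <- 2 * tcrossprod(Cin)
  D_act_mo <- rdm$D
  Gns <- nonseparable_2dm(rdm$G, rdm$D)
  D_act_ao <- Cact %*% D_act_mo %*% t(Cact)
  list(D_inactive = D_in, D_active = D_act_mo, Gamma = rdm$G, Gamma_ns = Gns,
       D_total = D_in + D_act_ao, Cact = Cact)
}

#' Electron density and gradient on grid points
#'
#' @param D total AO density matrix
#' @param grid a `qc_grid`
#' @return list with `rho` and `grad` (n x 3)
#' @export
density_on_grid <- function(D, grid) {
  rho <- numeric(length(grid$w)); gr <- matrix(0, length(grid$w), 3)
  for (ib in seq_along(grid$batches)) {
    idx <- grid$batches[[ib]]
    ao <- ao_block(grid, ib, deriv = TRUE)
    PD <- ao$val %*% D
    rho[idx] <- rowSums(PD * ao$val)
    gr[idx, 1] <- 2 * rowSums(PD * ao$dx)
    gr[idx, 2] <- 2 * rowSums(PD * ao$dy)
    gr[idx, 3] <- 2 * rowSums(PD * ao$dz)
  }
  if (min(rho) < -1e-10) stop("negative density on grid: AO values corrupted")
  list(rho = pmax(rho, 0), grad = gr)
}

#' Correlated on-top pair density on grid points
#'
#' `Pi(r) = 1/2 sum_tuvw G^ns_tuvw phi_t phi_u phi_v phi_w` over active MOs.
#'
#' @param Cact AO coefficients of the active MOs (nao x A)
#' @param Gns nonseparable active 2-RDM
#' @param grid a `qc_grid`
#' @return numeric vector Pi(r_g)
#' @export
ontop_on_grid <- function(Cact, Gns, grid) {
  A <- ncol(Cact)
  if (dim(Gns)[1] != A) stop("active MO count does not match the 2-RDM")
  Gm <- matrix(Gns, A * A, A * A)
  pi_c <- numeric(length(grid$w))
  for (ib in seq_along(grid$batches)) {
    idx <- grid$batches[[ib]]
    ao <- ao_block(grid, ib, deriv = TRUE)
    M <- ao$val %*% Cact
    n <- nrow(M)
    Mp <- matrix(0, n, A * A)
    for (t in seq_len(A)) Mp[, (t - 1) * A + seq_len(A)] <- M[, t] * M
    pi_c[idx] <- 0.5 * rowSums((Mp %*% Gm) * Mp)
  }
  pi_c
}

#' Translate density and on-top pair density to effective spin densities
#'
#' `rho_eff = rho/2 +- sqrt(-Pi)`; for `Pi > 0` the pair is complex conjugate
#' (complex regime). Effective spin gradients scale `grad rho` by
#' `(1 +- zeta_eff)/2` with `zeta_eff = 2 sqrt(-Pi)/rho`; the gradient of Pi
#' itself is not propagated.
#'
#' @param rho density (vector)
#' @param grad_rho gradient matrix (n x 3), optional
#' @param pi_corr correlated on-top pair density (vector)
#' @return list with complex `rho_a`, `rho_b`, `regime` ("real"/"complex"),
#'   and if gradients given, complex `grad_a`, `grad_b`
#' @export
translate <- function(rho, pi_corr, grad_rho = NULL) {
  if (any(pi_corr < -rho^2 / 4 - 1e-10))
    stop("on-top pair density below -rho^2/4: unphysical polarization")
  q <- sqrt(as.complex(-pi_corr))
  ra <- rho / 2 + q
  rb <- rho / 2 - q
  out <- list(rho_a = ra, rho_b = rb,
              regime = ifelse(pi_corr > 0, "complex", "real"))
  if (!is.null(grad_rho)) {
    zeta <- 2 * q / rho
    out$grad_a <- grad_rho / 2 * (1 + zeta)
    out$grad_b <- grad_rho / 2 * (1 - zeta)
  }
  out
}

.translated_funs <- c(ctlda = "lda", ctpbe = "pbe", ctblyp = "blyp",
                      tlda = "lda", tpbe = "pbe", tblyp = "blyp")

#' Evaluate a translated pair-density functional on a point stream
#'
#' Returns the (real) energy density per volume and its exact partial
#' derivatives with respect to density, squared density gradient and
#' correlated on-top pair density. The `ct*` functionals use the complex
#' translation for `Pi > 0`; the real-only `t*` variants clamp `Pi` at zero.
#'
#' @param functional_id one of `"ctLDA"`, `"ctPBE"`, `"ctBLYP"` (or the
#'   real-only `"tLDA"`, `"tPBE"`, `"tBLYP"`)
#' @param rho,sigma,pi_corr per-point density, |grad rho|^2 and on-top values
#' @return list with `exc`, `vrho`, `vsigma`, `vpi`, `regime`
#' @export
eval_xc <- function(functional_id, rho, sigma, pi_corr) {
  fid <- tolower(functional_id)
  if (!fid %in% names(.translated_funs))
    stop("unknown translated functional: ", functional_id)
  if (startsWith(fid, "t")) pi_corr <- pmin(pi_corr, 0)
  cpp_xc_translated(.fun_code(.translated_funs[[fid]]), rho, sigma, pi_corr)
}

is_gga <- function(functional_id) {
  !grepl("lda$", tolower(functional_id))
}

#' Translated exchange-correlation energy on a grid
#'
#' @param grid a `qc_grid`
#' @param dens list with `rho`, `grad` (from [density_on_grid()]) and `pi`
#'   (from [ontop_on_grid()])
#' @param functional_id translated functional name
#' @return E_xc in Hartree
#' @export
xc_energy <- function(grid, dens, functional_id) {
  live <- dens$rho > 1e-12
  sig <- rowSums(dens$grad^2)
  k <- eval_xc(functional_id, pmax(dens$rho, 1e-12), sig, dens$pi)
  sum(grid$w * k$exc * live)
}

# one-pass PDFT XC build: E_xc, AO-basis v_xc and the w_xc tensor
# (nao x A^3 matrix, column index packs (u,v,w) with u fastest)
pdft_xc_build <- function(grid, D_total, Cact, Gns, functional_id,
                          want_wxc = TRUE) {
  gga <- is_gga(functional_id)
  A <- ncol(Cact)
  nao <- grid$n_ao
  Gm <- matrix(Gns, A * A, A * A)
  V <- matrix(0, nao, nao)
  W <- if (want_wxc) matrix(0, nao, A * A * A) else NULL
  E <- 0
  n_complex <- 0L
  for (ib in seq_along(grid$batches)) {
    idx <- grid$batches[[ib]]
    ao <- ao_block(grid, ib, deriv = TRUE)
    Phi <- ao$val
    PD <- Phi %*% D_total
    rho <- rowSums(PD * Phi)
    gx <- 2 * rowSums(PD * ao$dx); gy <- 2 * rowSums(PD * ao$dy); gz <- 2 * rowSums(PD * ao$dz)
    sig <- gx^2 + gy^2 + gz^2
    M <- Phi %*% Cact
    n <- nrow(M)
    Mp <- matrix(0, n, A * A)
    for (t in seq_len(A)) Mp[, (t - 1) * A + seq_len(A)] <- M[, t] * M
    pi_c <- 0.5 * rowSums((Mp %*% Gm) * Mp)
    live <- rho > 1e-12
    k <- eval_xc(functional_id, pmax(rho, 1e-12), sig, pi_c)
    w <- grid$w[idx] * live
    E <- E + sum(w * k$exc)
    n_complex <- n_complex + sum(k$regime * live)
    B <- (w * k$vrho) * Phi
    if (gga) {
      vs <- w * k$vsigma
      Cm <- 2 * (vs * gx * ao$dx + vs * gy * ao$dy + vs * gz * ao$dz)
      V <- V + crossprod(Phi, B + Cm) + crossprod(Cm, Phi)
    } else {
      V <- V + crossprod(Phi, B)
    }
    if (want_wxc) {
      # W[mu, uvw] += sum_g w vpi chi_mu phi_u phi_v phi_w
      wp <- w * k$vpi
      Mt <- matrix(0, n, A * A * A)
      for (t in seq_len(A))
        Mt[, (t - 1) * A * A + seq_len(A * A)] <- M[, t] * Mp
      W <- W + crossprod(Phi, wp * Mt)
    }
  }
  list(E_xc = E, v_xc = (V + t(V)) / 2, w_xc = W, n_complex = n_complex)
}

#' Total MC-PDFT energy
#'
#' Kohn-Sham-like assembly: core + classical Coulomb of the total density +
#' translated exchange-correlation + nuclear repulsion. There is no exact
#' exchange term; kinetic energy enters through the wave function via
#' `Tr(h D)`.
#'
#' @param sys `qc_system`
#' @param dmats density matrices (from a converged state or [build_dmats()])
#' @param functional_id translated functional
#' @param grid `qc_grid`
#' @param ints,eri integral handles
#' @return `EnergyReport` list: `E_total` plus components
#' @export
total_energy <- function(sys, dmats, functional_id, grid, ints, eri) {
  D <- dmats$D_total
  J <- coulomb_matrix(eri, D)
  xc <- pdft_xc_build(grid, D, dmats$Cact, dmats$Gamma_ns, functional_id,
                      want_wxc = FALSE)
  rep_ <- list(E_nuc = sys$E_nuc,
               E_core = sum(ints$hcore * D),
               E_coulomb = 0.5 * sum(D * J),
               E_xc = xc$E_xc,
               functional = functional_id)
  rep_$E_total <- rep_$E_nuc + rep_$E_core + rep_$E_coulomb + rep_$E_xc
  class(rep_) <- "energy_report"
  rep_
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("MC-PDFT(%s) energy: %.10f Ha\n", x$functional, x$E_total))
  cat(sprintf("  E_nuc %12.8f  E_core %14.8f  E_J %12.8f  E_xc %12.8f\n",
              x$E_nuc, x$E_core, x$E_coulomb, x$E_xc))
  invisible(x)
}
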