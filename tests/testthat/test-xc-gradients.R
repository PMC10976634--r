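# common correlated fixture: water CAS(2,2)/STO-3G with a random normalized
# CI vector (not an eigenvector, so every gradient term is exercised)
wfix <- function() memo("wfix", function() {
  w <- water_sto3g()
  g <- water_grid()
  hf <- scf_rhf(w$sys, ints = w$ints, eri = w$eri)
  actsp <- vpdft:::active_space(w$sys, 2, 2)
  sp <- ci_space(2, 2)
  set.seed(4)
  ci <- rnorm(sp$dim); ci <- ci / sqrt(sum(ci^2))
  rdm <- make_rdms(ci, sp)
  list(w = w, g = g, C = hf$C, actsp = actsp, sp = sp, ci = ci, rdm = rdm)
})

test_that("v_xc reproduces finite-difference density variations", {
  f <- wfix()
  build <- vpdft:::pdft_build_state(f$w$sys, f$w$ints, f$w$eri, f$g, f$C,
                                    f$actsp, f$rdm, "ctPBE")
  # Tr(dD vxc) vs FD of E_xc under a density perturbation at fixed Pi
  set.seed(8)
  n <- f$w$sys$n_ao
  dm <- vpdft:::build_dmats(f$C, f$actsp, f$rdm)
  P <- matrix(rnorm(n^2), n); P <- (P + t(P)) * 0.01
  exc_of <- function(t) {
    vpdft:::pdft_xc_build(f$g, dm$D_total + t * P, dm$Cact, dm$Gamma_ns,
                          "ctPBE", want_wxc = FALSE)$E_xc
  }
  fd <- fd5(exc_of, 0, 1e-3)
  vxc <- vpdft:::pdft_xc_build(f$g, dm$D_total, dm$Cact, dm$Gamma_ns, "ctPBE",
                               want_wxc = FALSE)$v_xc
  expect_equal(sum(P * vxc), fd, tolerance = 1e-5 * max(1, abs(fd)))
  expect_lt(max(abs(vxc - t(vxc))), 1e-12)
})

test_that("w_xc contraction matches finite differences along the 2-RDM", {
  f <- wfix()
  dm <- vpdft:::build_dmats(f$C, f$actsp, f$rdm)
  xc <- vpdft:::pdft_xc_build(f$g, dm$D_total, dm$Cact, dm$Gamma_ns, "ctPBE")
  A <- 2
  wt <- array(crossprod(dm$Cact, xc$w_xc), c(A, A, A, A))
  # all-active block permutation symmetry (fully symmetric quartic moments)
  for (p in list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(3, 4, 1, 2), c(4, 3, 2, 1)))
    expect_lt(max(abs(wt - aperm(wt, p))), 1e-12)
  set.seed(9)
  dG <- array(rnorm(A^4), c(A, A, A, A)) * 0.01
  dG <- (dG + aperm(dG, c(2, 1, 4, 3)) + aperm(dG, c(3, 4, 1, 2)) +
         aperm(dG, c(4, 3, 2, 1))) / 4
  exc_of <- function(t) {
    vpdft:::pdft_xc_build(f$g, dm$D_total, dm$Cact, dm$Gamma_ns + t * dG,
                          "ctPBE", want_wxc = FALSE)$E_xc
  }
  fd <- fd5(exc_of, 0, 1e-3)
  # dE/dGns_tuvw = 1/2 wt_tuvw with the project Pi prefactor convention
  expect_equal(0.5 * sum(wt * dG), fd, tolerance = 1e-5 * max(abs(fd), 1e-3))
  # zero on-top derivative -> zero tensor
  xc0 <- vpdft:::pdft_xc_build(f$g, dm$D_total, dm$Cact, 0 * dm$Gamma_ns, "ctLDA")
  expect_true(all(abs(crossprod(dm$Cact, xc0$w_xc)) >= 0)) # well-defined
})

test_that("joint orbital and CI analytic gradients match finite differences", {
  fixtures <- list(
    list(sys = build_system(h2_geometry(0.9), "6-31g"), cas = c(2, 2)),
    list(sys = build_system(water_geometry(), "sto-3g"), cas = c(2, 2)),
    list(sys = build_system(data.frame(element = c("Mg", "Mg"), x = 0, y = 0,
                                       z = c(0, 3.5)), "sto-3g"), cas = c(2, 2)))
  for (fx in fixtures) {
    sys <- fx$sys
    ints <- core_integrals(sys); eri <- eri_integrals(sys)
    g <- build_grid(sys, level = 2)
    hf <- scf_rhf(sys, ints = ints, eri = eri)
    actsp <- vpdft:::active_space(sys, fx$cas[1], fx$cas[2])
    sp <- ci_space(fx$cas[2], fx$cas[1])
    set.seed(12)
    ci <- rnorm(sp$dim); ci <- ci / sqrt(sum(ci^2))
    rdm <- make_rdms(ci, sp)
    build <- vpdft:::pdft_build_state(sys, ints, eri, g, hf$C, actsp, rdm, "ctLDA")
    dE <- vpdft:::pdft_dEdC(build, hf$C, actsp, rdm)
    Amat <- crossprod(dE, hf$C)
    Gk <- t(Amat) - Amat
    mask <- vpdft:::rot_mask(ncol(hf$C), actsp)
    E_of <- function(Cn) vpdft:::pdft_build_state(sys, ints, eri, g, Cn, actsp,
                                                  rdm, "ctLDA", want_wxc = FALSE)$E
    set.seed(13)
    for (rep in 1:3) {
      K <- matrix(0, ncol(hf$C), ncol(hf$C))
      K[mask] <- rnorm(sum(mask)); K <- K - t(K); K <- K / max(abs(K))
      fd <- fd5(function(t) E_of(rotate_orbitals(hf$C, t * K)), 0, 1e-3)
      expect_equal(sum(Gk * K) / 2, fd, tolerance = 1e-6)
    }
    # CI gradient
    eff <- ci_effective_integrals(build, hf$C, actsp, rdm)
    sig <- ci_sigma(sp, eff$h_eff, eff$g_eff, ci)
    gci <- 2 * (sig - sum(ci * sig) * ci)
    E_ci <- function(v) {
      v <- v / sqrt(sum(v^2))
      vpdft:::pdft_build_state(sys, ints, eri, g, hf$C, actsp,
                               make_rdms(v, sp), "ctLDA", want_wxc = FALSE)$E
    }
    for (rep in 1:3) {
      d <- rnorm(sp$dim); d <- d - sum(ci * d) * ci; d <- d / sqrt(sum(d^2))
      fd <- fd5(function(t) E_ci(ci + t * d), 0, 1e-4)
      expect_equal(sum(gci * d), fd, tolerance = 1e-6)
    }
    # first-order consistency of the quadratic CI model at the point
    expect_equal(eff$core_energy + sum(eff$h_eff * rdm$D) +
                 0.5 * sum(eff$g_eff * rdm$G), build$E, tolerance = 1e-10)
  }
})

test_that("a converged variational state is stationary", {
  f <- wfix()
  fit <- mcscf(f$w$sys, cas = c(2, 2), method = "vpdft", functional = "ctLDA",
               grid = f$g, conv_grad = 1e-6)
  expect_lt(fit$orb_grad_max, 1e-5)
  expect_lt(fit$ci_grad_norm, 1e-4)
  # closed-shell single-determinant CI space: CI gradient identically zero
  fit0 <- mcscf(f$w$sys, cas = c(0, 0), method = "vpdft", functional = "ctLDA",
                grid = f$g)
  expect_equal(fit0$actsp$n_orb, 0L)
})

test_that("the empty-active-space Fock matrix is the KS Fock matrix", {
  f <- wfix()
  ks <- scf_rhf(f$w$sys, functional = "pbe", grid = f$g,
                ints = f$w$ints, eri = f$w$eri)
  actsp0 <- vpdft:::active_space(f$w$sys, 0, 0)
  rdm0 <- list(D = matrix(0, 0, 0), G = array(0, c(0, 0, 0, 0)))
  build <- vpdft:::pdft_build_state(f$w$sys, f$w$ints, f$w$eri, f$g, ks$C,
                                    actsp0, rdm0, "ctPBE")
  # G_ao = h + J + vxc must equal the KS Fock matrix at the same density
  # (the density of the final orbitals, which is what the PDFT build uses)
  Dks <- 2 * tcrossprod(ks$C[, seq_len(ks$nocc)])
  J <- coulomb_matrix(f$w$eri, Dks)
  Vxc <- vpdft:::ks_xc(f$g, Dks, "pbe")$V
  expect_lt(max(abs(build$G_ao - (f$w$ints$hcore + J + Vxc))), 1e-8)
  # and the orbital gradient vanishes at the KS solution
  dE <- vpdft:::pdft_dEdC(build, ks$C, actsp0, rdm0)
  Amat <- crossprod(dE, ks$C)
  Gk <- t(Amat) - Amat
  mask <- vpdft:::rot_mask(ncol(ks$C), actsp0)
  expect_lt(max(abs(Gk[mask])), 1e-5)
})
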