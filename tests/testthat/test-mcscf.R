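test_that("orbital rotations preserve orthonormality", {
  w <- water_sto3g()
  hf <- scf_rhf(w$sys, ints = w$ints, eri = w$eri)
  n <- ncol(hf$C)
  expect_identical(rotate_orbitals(hf$C, matrix(0, n, n)), hf$C %*% diag(n))
  set.seed(14)
  K <- matrix(rnorm(n^2), n) * 0.1; K <- K - t(K)
  C2 <- rotate_orbitals(hf$C, K)
  expect_lt(max(abs(crossprod(C2, w$ints$S %*% C2) - diag(n))), 1e-12)
  expect_error(rotate_orbitals(hf$C, matrix(1, n, n)), "antisymmetric")
  # exp(-K1)exp(-K2) ~ exp(-(K1+K2)) for commuting blocks
  K1 <- matrix(0, n, n); K1[1, 2] <- 0.05; K1 <- K1 - t(K1)
  K2 <- matrix(0, n, n); K2[3, 4] <- 0.07; K2 <- K2 - t(K2)
  expect_lt(max(abs(vpdft:::expm_antisym(K1) %*% vpdft:::expm_antisym(K2) -
                    vpdft:::expm_antisym(K1 + K2))), 1e-12)
})

test_that("CASSCF matches direct black-box minimization over all parameters", {
  # independent route: minimize the raw energy expression with optim() over
  # packed orbital-rotation parameters and the CI vector simultaneously
  w <- water_sto3g()
  fit <- mcscf(w$sys, cas = c(2, 2), method = "casscf", conv_grad = 1e-7)
  actsp <- fit$actsp; sp <- fit$space
  mask <- vpdft:::rot_mask(ncol(fit$C), actsp)
  nk <- sum(mask)
  C0 <- fit$C
  target <- function(par) {
    K <- matrix(0, ncol(C0), ncol(C0))
    K[mask] <- par[seq_len(nk)]
    K <- K - t(K)
    ci <- par[-seq_len(nk)]
    ci <- ci / sqrt(sum(ci^2))
    Cn <- rotate_orbitals(C0, K)
    rdm <- make_rdms(ci, sp)
    vpdft:::casscf_energy_fixed(w$sys, w$ints, w$eri, Cn, actsp, rdm)
  }
  # CASSCF has several local solutions (different active-orbital character),
  # and quasi-Newton minimisers can tunnel between them; the independent
  # certificate is local: the raw energy expression is stationary at the fit
  # and increases in every sampled direction around it
  expect_equal(target(c(rep(0, nk), fit$ci)), fit$E, tolerance = 1e-10)
  set.seed(15)
  for (sc in c(0.01, 0.05, 0.2)) {
    for (r in 1:25) {
      par <- c(rnorm(nk) * sc, fit$ci + rnorm(sp$dim) * 2 * sc)
      expect_gte(target(par), fit$E - 1e-9)
    }
  }
  # and the directional FD gradient vanishes at the solution
  set.seed(16)
  d <- rnorm(nk + sp$dim); d <- d / sqrt(sum(d^2))
  h <- 1e-5
  fd <- (target(c(rep(0, nk), fit$ci) + h * d) -
         target(c(rep(0, nk), fit$ci) - h * d)) / (2 * h)
  expect_lt(abs(fd), 1e-5)
})

test_that("restarting from a converged state exits immediately", {
  w <- water_sto3g()
  fit <- mcscf(w$sys, cas = c(2, 2), method = "casscf", conv_grad = 1e-7)
  fit2 <- mcscf(w$sys, cas = c(2, 2), method = "casscf", conv_grad = 1e-5,
                C0 = fit$C, ci0 = fit$ci)
  expect_lte(fit2$n_macro, 3L)
  expect_equal(fit2$E, fit$E, tolerance = 1e-10)
})

test_that("the fit is deterministic for identical inputs", {
  w <- water_sto3g()
  f1 <- mcscf(w$sys, cas = c(2, 2), method = "casscf")
  f2 <- mcscf(w$sys, cas = c(2, 2), method = "casscf")
  expect_identical(f1$E, f2$E)
  expect_identical(f1$C, f2$C)
})

test_that("variational optimization needs comparably many macro-iterations", {
  w <- water_sto3g()
  g <- water_grid()
  fc <- mcscf(w$sys, cas = c(2, 2), method = "casscf")
  fv <- mcscf(w$sys, cas = c(2, 2), method = "vpdft", functional = "ctPBE",
              grid = g)
  expect_lte(fv$n_macro, 3L * fc$n_macro + 5L)
})

test_that("single-point driver validates its configuration", {
  expect_error(run_single_point(list(geometry = water_geometry(),
                                     basis = "sto-3g", cas = c(2, 2),
                                     method = "xyz")), "unknown method")
  expect_error(run_single_point(list(geometry = "no/such/file.xyz",
                                     basis = "sto-3g", cas = c(2, 2))),
               "not found")
  fit <- run_single_point(list(geometry = water_geometry(), basis = "sto-3g",
                               cas = c(2, 2), method = "casscf"))
  expect_s3_class(fit, "mcscf")
  expect_true(fit$converged)
})

test_that("perturbative evaluation refuses unconverged input", {
  w <- water_sto3g()
  fit <- mcscf(w$sys, cas = c(2, 2), method = "casscf")
  broken <- fit
  broken$converged <- FALSE
  broken$orb_grad_max <- 0.2
  expect_error(perturbative_energy(broken, "ctPBE"), "converged")
})
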