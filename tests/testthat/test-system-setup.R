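test_that("system construction populates electron count and nuclear repulsion", {
  sys <- build_system(h2_geometry(0.74), "sto-3g")
  expect_equal(sys$n_ao, 2L)
  expect_equal(sys$n_electrons, 2L)
  expect_equal(sys$E_nuc, 1 / (0.74 / 0.52917721092), tolerance = 1e-12)
  he <- build_system(data.frame(element = "He", x = 0, y = 0, z = 0), "sto-3g")
  expect_equal(he$E_nuc, 0)
  expect_error(build_system(data.frame(element = "Xx", x = 0, y = 0, z = 0), "sto-3g"),
               "unknown element")
  expect_error(build_system(h2_geometry(0.7), "sto-3g", charge = 5),
               "negative electron count")
  expect_error(build_system(data.frame(element = character(0), x = numeric(0),
                                       y = numeric(0), z = numeric(0)), "sto-3g"),
               "empty")
})

test_that("one-electron matrices are symmetric with unit-normalised AOs", {
  w <- water_631g()
  expect_lt(max(abs(w$ints$S - t(w$ints$S))), 1e-14)
  expect_lt(max(abs(w$ints$hcore - t(w$ints$hcore))), 1e-12)
  expect_lt(max(abs(diag(w$ints$S) - 1)), 1e-10)
})

test_that("s-type integrals match the closed-form Gaussian oracle", {
  # H2 in 6-31G is an all-s system: every matrix element has an elementary form
  sys <- build_system(h2_geometry(0.74), "6-31g")
  ints <- core_integrals(sys)
  eri <- eri_integrals(sys)
  sh <- sys$shells
  # AO k comes from shell k here (all shells are single-s); contracted AOs
  # are linear combinations of primitives, so compare contracted values
  nao <- sys$n_ao
  contr <- function(f, i, j, ...) {
    v <- 0
    for (ka in seq_along(sh$exps[[i]])) for (kb in seq_along(sh$exps[[j]]))
      v <- v + sh$coefs[[i]][ka] * sh$coefs[[j]][kb] *
        f(sh$exps[[i]][ka], sh$exps[[j]][kb], sh$centers[i, ], sh$centers[j, ], ...)
    v
  }
  nrm <- vapply(seq_len(nao), function(i) 1 / sqrt(contr(oracle_s_overlap, i, i)), 0)
  for (i in 1:nao) for (j in 1:i) {
    expect_equal(ints$S[i, j], contr(oracle_s_overlap, i, j) * nrm[i] * nrm[j],
                 tolerance = 1e-10)
    expect_equal(ints$T[i, j], contr(oracle_s_kinetic, i, j) * nrm[i] * nrm[j],
                 tolerance = 1e-10)
    expect_equal(ints$V[i, j],
                 contr(oracle_s_nuclear, i, j, nuclei = sys$xyz, Z = sys$Z) * nrm[i] * nrm[j],
                 tolerance = 1e-10)
  }
  # a sample of two-electron integrals against the closed form
  contr4 <- function(i, j, k, l) {
    v <- 0
    for (ka in seq_along(sh$exps[[i]])) for (kb in seq_along(sh$exps[[j]]))
      for (kc in seq_along(sh$exps[[k]])) for (kd in seq_along(sh$exps[[l]]))
        v <- v + prod(sh$coefs[[i]][ka], sh$coefs[[j]][kb], sh$coefs[[k]][kc], sh$coefs[[l]][kd]) *
          oracle_s_eri(sh$exps[[i]][ka], sh$exps[[j]][kb], sh$exps[[k]][kc], sh$exps[[l]][kd],
                       sh$centers[i, ], sh$centers[j, ], sh$centers[k, ], sh$centers[l, ])
    v
  }
  set.seed(11)
  for (rep in 1:15) {
    q <- sample(nao, 4, replace = TRUE)
    expect_equal(vpdft:::cpp_eri_elem(eri, q[1], q[2], q[3], q[4]),
                 contr4(q[1], q[2], q[3], q[4]) * prod(nrm[q]),
                 tolerance = 1e-10)
  }
})

test_that("Coulomb matrix is linear, symmetric and positive on densities", {
  w <- water_sto3g()
  set.seed(2)
  n <- w$sys$n_ao
  A1 <- matrix(rnorm(n^2), n); D1 <- A1 + t(A1)
  A2 <- matrix(rnorm(n^2), n); D2 <- A2 + t(A2)
  J1 <- coulomb_matrix(w$eri, D1)
  J2 <- coulomb_matrix(w$eri, D2)
  J12 <- coulomb_matrix(w$eri, D1 + D2)
  expect_lt(max(abs(J12 - J1 - J2)), 1e-10)
  expect_lt(max(abs(J1 - t(J1))), 1e-12)
  expect_identical(coulomb_matrix(w$eri, 0 * D1), 0 * D1)
  Dp <- tcrossprod(matrix(rnorm(n * 2), n)) # positive semidefinite
  expect_gte(0.5 * sum(Dp * coulomb_matrix(w$eri, Dp)), 0)
  expect_error(coulomb_matrix(w$eri, diag(3)), "dimension")
})

test_that("rigid translation leaves the total energy unchanged", {
  g1 <- water_geometry()
  g2 <- g1
  g2$x <- g2$x + 1.7; g2$y <- g2$y - 0.4; g2$z <- g2$z + 0.9
  e1 <- scf_rhf(build_system(g1, "sto-3g"))$E
  e2 <- scf_rhf(build_system(g2, "sto-3g"))$E
  expect_equal(e1, e2, tolerance = 1e-8)
})

test_that("the quadrature grid integrates the density to the electron count", {
  w <- water_sto3g()
  hf <- scf_rhf(w$sys, ints = w$ints, eri = w$eri)
  errs <- sapply(1:3, function(lv) {
    g <- build_grid(w$sys, level = lv)
    abs(sum(g$w * density_on_grid(hf$D, g)$rho) - 10)
  })
  expect_lt(errs[2] / 10, 1e-4)
  # finer grids do not degrade the charge integration
  expect_lt(errs[3], errs[1] + 1e-9)
  expect_error(build_grid(list(atoms = character(0)), 3), "empty|level")
})
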