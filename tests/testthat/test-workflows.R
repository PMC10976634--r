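test_that("scan extraction interpolates minima and flags repulsive curves", {
  d <- seq(1, 3, by = 0.25)
  # synthetic Morse-like well with known minimum
  e <- 0.2 * (1 - exp(-1.3 * (d - 1.8)))^2 - 0.2
  sc <- vpdft:::scan_extract(d, e, "casscf", NULL, list(element = "X", basis = "b"))
  expect_lt(abs(sc$r_e - 1.8), 0.05)
  # asymptote is the last scanned point, not the analytic limit
  expect_lt(abs(sc$D_e - (e[length(e)] - min(e)) * 27.211386), 0.12)
  rep_curve <- vpdft:::scan_extract(d, exp(-d), "casscf", NULL,
                                    list(element = "X", basis = "b"))
  expect_true(is.na(rep_curve$D_e))
  expect_error(dissociation_scan("H", c(2, 1), "sto-3g", c(2, 2)), "ascending")
})

test_that("a real H2 scan produces a bound ctPBE curve with sane D_e", {
  sc <- dissociation_scan("H", c(0.55, 0.65, 0.74, 0.85, 1.0, 1.4, 2.2, 4.5),
                          "sto-3g", cas = c(2, 2), method = "vpdft",
                          functional = "ctPBE", grid_level = 2, conv_grad = 1e-4)
  expect_false(is.na(sc$D_e))
  expect_gt(sc$D_e, 3); expect_lt(sc$D_e, 6.5)
  expect_gt(sc$r_e, 0.6); expect_lt(sc$r_e, 0.9)
  # warm-started curve is monotone towards the asymptote beyond the minimum
  post <- sc$energies[sc$distances >= sc$r_e]
  expect_true(all(diff(post) > -1e-6))
})

test_that("natural occupations are physical and closed-shell limits exact", {
  w <- water_sto3g()
  fit <- mcscf(w$sys, cas = c(2, 2), method = "casscf")
  no <- natural_occupations(fit)
  expect_length(no, 2)
  expect_true(all(no >= 0 & no <= 2))
  expect_equal(sum(no), 2, tolerance = 1e-10)
  # closed-shell single-determinant state: occupations exactly {2, 0}
  sp <- fit$space
  v <- numeric(sp$dim); v[1] <- 1
  fit2 <- fit
  fit2$rdm <- make_rdms(v, sp)
  expect_equal(natural_occupations(fit2), c(2, 0), tolerance = 1e-12)
})

test_that("dipole moments vanish by symmetry and obey Hellmann-Feynman", {
  sysh <- build_system(h2_geometry(0.9), "sto-3g")
  fh <- mcscf(sysh, cas = c(2, 2), method = "casscf")
  expect_lt(max(abs(dipole_moment(fh))), 1e-6)
  # field-derivative oracle: E(eps) with h += eps . r, mu = -dE/deps
  w <- water_sto3g()
  g <- water_grid()
  fit <- mcscf(w$sys, cas = c(2, 2), method = "vpdft", functional = "ctBLYP",
               grid = g, conv_grad = 1e-6)
  mu <- dipole_moment(fit, unit = "au")
  eps <- 5e-4
  E_field <- function(f) {
    ints2 <- w$ints
    ints2$hcore <- vpdft:::field_hcore(w$ints, f)
    fitf <- mcscf(w$sys, cas = c(2, 2), method = "vpdft", functional = "ctBLYP",
                  grid = g, ints = ints2, eri = w$eri, conv_grad = 1e-6,
                  C0 = fit$C, ci0 = fit$ci)
    fitf$E - sum(vpdft:::nuclear_dipole(w$sys) * f)
  }
  fd_mu <- -(E_field(c(0, 0, eps)) - E_field(c(0, 0, -eps))) / (2 * eps)
  expect_equal(mu[3], fd_mu, tolerance = 1e-4 / 2.541746)
  # the perturbative state misses the wave-function response: its
  # expectation-value dipole deviates more from the field derivative
  cas <- mcscf(w$sys, cas = c(2, 2), method = "casscf", conv_grad = 1e-7)
  pp <- perturbative_energy(cas, "ctBLYP", grid = g)
  mu_p <- dipole_moment(pp, unit = "au")
  E_field_p <- function(f) {
    ints2 <- w$ints
    ints2$hcore <- vpdft:::field_hcore(w$ints, f)
    casf <- mcscf(w$sys, cas = c(2, 2), method = "casscf", ints = ints2,
                  eri = w$eri, conv_grad = 1e-7, C0 = cas$C, ci0 = cas$ci)
    ppf <- perturbative_energy(casf, "ctBLYP", grid = g)
    ppf$E - sum(vpdft:::nuclear_dipole(w$sys) * f)
  }
  fd_mu_p <- -(E_field_p(c(0, 0, eps)) - E_field_p(c(0, 0, -eps))) / (2 * eps)
  expect_gt(abs(mu_p[3] - fd_mu_p), abs(mu[3] - fd_mu))
})

test_that("active-space ladders are monotone for the variational methods", {
  w <- water_sto3g()
  lad <- active_space_ladder(w$sys, list(c(2, 2), c(4, 4), c(6, 5)),
                             functional = "ctPBE", grid_level = 2,
                             conv_grad = 1e-4)
  expect_true(all(diff(lad$E_casscf) < 1e-8))
  expect_true(all(diff(lad$E_vpdft) < 1e-8))
  expect_warning(active_space_ladder(w$sys, list(c(4, 4), c(2, 2))), "nested")
})

test_that("basis handling reads bundled sets and rejects unknowns", {
  bs <- load_basis("sto-3g")
  expect_s3_class(bs, "qc_basis")
  expect_true(all(c("H", "O", "C") %in% names(bs$elements)))
  expect_error(load_basis("no-such-basis"), "not found")
  expect_error(build_system(data.frame(element = "Cu", x = 0, y = 0, z = 0),
                            "sto-3g", multiplicity = 2), "no entry")
  # synthetic even-tempered set covers the metal dimers with f functions
  met <- load_basis("synthetic-etzv")
  expect_true(all(c("Mg", "Cu") %in% names(met$elements)))
  expect_true(any(sapply(met$elements$Cu, function(s) s$l == 3L)))
})

test_that("XYZ files round-trip through the reader", {
  tf <- tempfile(fileext = ".xyz")
  writeLines(c("3", "water comment", "O 0.0 0.0 0.0",
               "H 0.757 0.0 0.586", "H -0.757 0.0 0.586"), tf)
  g <- read_xyz(tf)
  expect_equal(g$element, c("O", "H", "H"))
  expect_equal(g$x[2], 0.757)
  sys <- build_system(tf, "sto-3g")
  expect_equal(sys$n_electrons, 10L)
})
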