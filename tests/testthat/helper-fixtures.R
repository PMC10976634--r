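# Shared fixtures and independent oracles for the test suite.
# Fixtures are built in code; heavier shared objects are memoised per session.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

water_geometry <- function(scale = 1) {
  ang <- 104.52 * pi / 180
  r <- 0.9572 * scale
  data.frame(element = c("O", "H", "H"),
             x = c(0, r * sin(ang / 2), -r * sin(ang / 2)),
             y = 0,
             z = c(0, r * cos(ang / 2), r * cos(ang / 2)))
}

h2_geometry <- function(d_angstrom) {
  data.frame(element = c("H", "H"), x = 0, y = 0, z = c(0, d_angstrom))
}

water_sto3g <- function() memo("water_sto3g", function() {
  sys <- build_system(water_geometry(), "sto-3g")
  list(sys = sys, ints = core_integrals(sys), eri = eri_integrals(sys))
})

water_631g <- function() memo("water_631g", function() {
  sys <- build_system(water_geometry(), "6-31g")
  list(sys = sys, ints = core_integrals(sys), eri = eri_integrals(sys))
})

water_grid <- function(level = 2) memo(paste0("wgrid", level), function() {
  build_grid(water_sto3g()$sys, level = level)
})

# ---------------- closed-form s-Gaussian oracles (independent of the
# McMurchie-Davidson engine; elementary erf/exponential formulas) ----------

.erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
.F0 <- function(T) ifelse(T < 0.01,
                          1 - T / 3 + T^2 / 10 - T^3 / 42 + T^4 / 216 - T^5 / 1320,
                          0.5 * sqrt(pi / T) * .erf(sqrt(T)))
.snorm <- function(a) (2 * a / pi)^0.75

oracle_s_overlap <- function(a, b, A, B) {
  p <- a + b
  .snorm(a) * .snorm(b) * exp(-a * b / p * sum((A - B)^2)) * (pi / p)^1.5
}

oracle_s_kinetic <- function(a, b, A, B) {
  p <- a + b; mu <- a * b / p; R2 <- sum((A - B)^2)
  .snorm(a) * .snorm(b) * mu * (3 - 2 * mu * R2) * exp(-mu * R2) * (pi / p)^1.5
}

oracle_s_nuclear <- function(a, b, A, B, nuclei, Z) {
  p <- a + b
  P <- (a * A + b * B) / p
  v <- 0
  for (n in seq_len(nrow(nuclei)))
    v <- v - Z[n] * 2 * pi / p * exp(-a * b / p * sum((A - B)^2)) *
      .F0(p * sum((P - nuclei[n, ])^2))
  .snorm(a) * .snorm(b) * v
}

oracle_s_eri <- function(a, b, c, d, A, B, C, D) {
  p <- a + b; q <- c + d
  P <- (a * A + b * B) / p; Q <- (c * C + d * D) / q
  K <- exp(-a * b / p * sum((A - B)^2)) * exp(-c * d / q * sum((C - D)^2))
  w <- p * q / (p + q)
  .snorm(a) * .snorm(b) * .snorm(c) * .snorm(d) *
    2 * pi^2.5 / (p * q * sqrt(p + q)) * K * .F0(w * sum((P - Q)^2))
}

# ---------------- Slater-Condon dense CAS Hamiltonian (independent CI
# oracle over explicit spin-orbital determinants) --------------------------

# determinants: list of sorted spin-orbital index vectors; spin orbital
# 2*k-1 = (orbital k, alpha), 2*k = (orbital k, beta)
sc_determinants <- function(n_orb, n_alpha, n_beta) {
  av <- utils::combn(seq_len(n_orb), n_alpha, simplify = FALSE)
  bv <- if (n_beta > 0) utils::combn(seq_len(n_orb), n_beta, simplify = FALSE) else list(integer(0))
  dets <- list()
  for (bb in bv) for (aa in av)
    dets[[length(dets) + 1L]] <- sort(c(2L * aa - 1L, 2L * bb))
  dets
}

sc_orb <- function(so) (so + 1L) %/% 2L
sc_spin <- function(so) so %% 2L # 1 = alpha, 0 = beta

# annihilate spin-orbital from det, returning sign and remaining det
sc_excite <- function(det, from, to) {
  i <- match(from, det)
  if (is.na(i) || to %in% det) return(NULL)
  rest <- det[-i]
  sgn <- (-1)^(i - 1)
  j <- sum(rest < to)
  list(det = sort(c(rest, to)), sign = sgn * (-1)^j)
}

# <D1|H|D2> with one-electron h (orbitals) and chemists' (tu|vw) integrals
sc_element <- function(d1, d2, h1, g4) {
  diff1 <- setdiff(d1, d2); diff2 <- setdiff(d2, d1)
  nd <- length(diff1)
  gg <- function(p, q, r, s) g4[sc_orb(p), sc_orb(q), sc_orb(r), sc_orb(s)]
  if (nd == 0) {
    e <- sum(vapply(d1, function(p) h1[sc_orb(p), sc_orb(p)], 0))
    for (p in d1) for (q in d1) {
      e <- e + 0.5 * gg(p, p, q, q)
      if (sc_spin(p) == sc_spin(q)) e <- e - 0.5 * gg(p, q, q, p)
    }
    return(e)
  }
  if (nd == 1) {
    p <- diff1; q <- diff2
    if (sc_spin(p) != sc_spin(q)) return(0)
    # sign: align the two determinants
    ex <- sc_excite(d2, q, p)
    if (is.null(ex) || !identical(ex$det, sort(d1))) return(0)
    e <- h1[sc_orb(p), sc_orb(q)]
    for (r in intersect(d1, d2)) {
      e <- e + gg(p, q, r, r)
      if (sc_spin(p) == sc_spin(r)) e <- e - gg(p, r, r, q)
    }
    return(ex$sign * e)
  }
  if (nd == 2) {
    p <- diff1[1]; r <- diff1[2]; q <- diff2[1]; s <- diff2[2]
    val <- 0
    # both assignments (q->p, s->r) and (q->r, s->p) with proper signs
    for (asg in list(c(1, 2), c(2, 1))) {
      pq <- diff2[asg[1]]; rs <- diff2[asg[2]]
      if (sc_spin(p) != sc_spin(pq) || sc_spin(r) != sc_spin(rs)) next
      ex1 <- sc_excite(d2, pq, p)
      if (is.null(ex1)) next
      ex2 <- sc_excite(ex1$det, rs, r)
      if (is.null(ex2) || !identical(ex2$det, sort(d1))) next
      val <- val + ex1$sign * ex2$sign * gg(p, pq, r, rs)
    }
    return(val)
  }
  0
}

sc_dense_h <- function(n_orb, n_alpha, n_beta, h1, g4) {
  dets <- sc_determinants(n_orb, n_alpha, n_beta)
  n <- length(dets)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    H[i, j] <- sc_element(dets[[i]], dets[[j]], h1, g4)
  (H + t(H)) / 2
}

# random symmetric two-electron tensor with the full integral symmetries
random_g4 <- function(A, seed = 1) {
  set.seed(seed)
  g <- array(rnorm(A^4), c(A, A, A, A))
  # symmetrise: (tu|vw) = (ut|vw) = (tu|wv) = (vw|tu)
  g <- g + aperm(g, c(2, 1, 3, 4))
  g <- g + aperm(g, c(1, 2, 4, 3))
  g <- g + aperm(g, c(3, 4, 1, 2))
  g / 8
}

fd5 <- function(f, x, h) {
  (-f(x + 2 * h) + 8 * f(x + h) - 8 * f(x - h) + f(x - 2 * h)) / (12 * h)
}
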