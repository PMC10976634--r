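# MO-basis integral transforms built on Coulomb builds of pair densities.
# For A active orbitals this costs A(A+1)/2 J-builds on the packed AO ERIs,
# which is cheap for the small active spaces this package targets.

# list of AO Coulomb matrices J[(vw)] for all active pairs v<=w
active_pair_J <- function(eri, Cact) {
  A <- ncol(Cact)
  Ds <- list()
  ij <- list()
  for (v in seq_len(A)) for (w in v:A) {
    Dp <- tcrossprod(Cact[, v], Cact[, w])
    Ds[[length(Ds) + 1L]] <- (Dp + t(Dp)) / 2
    ij[[length(ij) + 1L]] <- c(v, w)
  }
  Js <- coulomb_matrix(eri, Ds)
  list(J = Js, pairs = ij)
}

# active-active two-electron integrals (tu|vw), A^4 array
active_eri <- function(eri, Cact) {
  A <- ncol(Cact)
  pj <- active_pair_J(eri, Cact)
  g <- array(0, c(A, A, A, A))
  for (k in seq_along(pj$J)) {
    v <- pj$pairs[[k]][1]; w <- pj$pairs[[k]][2]
    blk <- crossprod(Cact, pj$J[[k]] %*% Cact) # (tu|vw) over all tu
    g[, , v, w] <- blk
    g[, , w, v] <- blk
  }
  g
}

# (pu|vw) with one general MO index p: returns array [nmo, A, A, A]
general_active_eri <- function(eri, Cmo, Cact) {
  A <- ncol(Cact)
  n <- ncol(Cmo)
  pj <- active_pair_J(eri, Cact)
  g <- array(0, c(n, A, A, A))
  for (k in seq_along(pj$J)) {
    v <- pj$pairs[[k]][1]; w <- pj$pairs[[k]][2]
    blk <- crossprod(Cmo, pj$J[[k]] %*% Cact) # (pu|vw)
    g[, , v, w] <- blk
    g[, , w, v] <- blk
  }
  g
}

# active ERIs from a precomputed pair-J list
active_eri_from_pj <- function(pj, Cact) {
  A <- ncol(Cact)
  g <- array(0, c(A, A, A, A))
  for (k in seq_along(pj$J)) {
    v <- pj$pairs[[k]][1]; w <- pj$pairs[[k]][2]
    blk <- crossprod(Cact, pj$J[[k]] %*% Cact)
    g[, , v, w] <- blk
    g[, , w, v] <- blk
  }
  g
}
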