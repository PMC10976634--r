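#' Restricted SCF (Hartree-Fock or Kohn-Sham)
#'
#' Closed-shell self-consistent field with DIIS acceleration and optional
#' level shifting. With `functional = NULL` this is restricted Hartree-Fock;
#' otherwise a restricted Kohn-Sham calculation with the named spin-density
#' functional (`"lda"`, `"pbe"`, `"blyp"`) evaluated on the molecular grid.
#' The KS path here is the plain spin-DFT route (no on-top translation); it
#' serves both as an orbital-guess generator and as the single-determinant
#' reference that translated-functional energies must reproduce.
#'
#' @param sys a `qc_system`
#' @param functional NULL for HF, or one of "lda", "pbe", "blyp"
#' @param grid a grid from [build_grid()] (built automatically if needed)
#' @param ints,eri precomputed integrals (optional, computed if missing)
#' @param max_iter,conv_grad convergence controls (commutator norm, Ha)
#' @param level_shift virtual-orbital level shift in Ha (helps metal dimers)
#' @param guess `"gwh"` (generalized Wolfsberg-Helmholz) or `"core"`
#' @param D0 optional starting AO density matrix
#' @param verbose print iteration trace
#' @return object of class `scf` with orbitals `C`, energies `eps`, `E`,
#'   density `D`, and the integral handles
#' @export
scf_rhf <- function(sys, functional = NULL, grid = NULL, ints = NULL, eri = NULL,
                    max_iter = 120L, conv_grad = 1e-7, level_shift = 0,
                    guess = c("gwh", "core"), D0 = NULL, verbose = FALSE) {
  guess <- match.arg(guess)
  if (is.null(ints)) ints <- core_integrals(sys)
  if (is.null(eri)) eri <- eri_integrals(sys)
  if (!is.null(functional) && is.null(grid)) grid <- build_grid(sys)
  S <- ints$S; h <- ints$hcore
  nao <- sys$n_ao
  if (sys$n_electrons %% 2L != 0L)
    stop("scf_rhf needs an even electron count; use scf_uhf for open shells")
  nocc <- sys$n_electrons %/% 2L
  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > 1e-8 * max(es$values)
  X <- es$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(es$values[keep]))
  fock_of <- function(D) {
    if (is.null(functional)) {
      jk <- coulomb_matrix(eri, D, exchange = TRUE)
      F <- h + jk$J - 0.5 * jk$K
      Eel <- sum(D * h) + 0.5 * sum(D * jk$J) - 0.25 * sum(D * jk$K)
    } else {
      J <- coulomb_matrix(eri, D)
      xc <- ks_xc(grid, D, functional)
      F <- h + J + xc$V
      Eel <- sum(D * h) + 0.5 * sum(D * J) + xc$E
    }
    list(F = F, Eel = Eel)
  }
  D <- if (!is.null(D0)) D0 else {
    F0 <- if (guess == "core") h else gwh_guess(h, S)
    C0 <- solve_fock(F0, X)
    2 * tcrossprod(C0[, seq_len(nocc), drop = FALSE])
  }
  diis <- diis_new()
  E <- NA_real_
  for (it in seq_len(max_iter)) {
    fo <- fock_of(D)
    E <- fo$Eel + sys$E_nuc
    # DIIS error = F D S - S D F in orthonormal basis
    err <- crossprod(X, (fo$F %*% D %*% S - S %*% D %*% fo$F) %*% X)
    gnorm <- max(abs(err))
    if (verbose) message(sprintf("SCF %3d  E = %.10f  |FDS-SDF| = %.2e", it, E, gnorm))
    if (gnorm < conv_grad && it > 1) {
      C <- solve_fock(fo$F, X)
      eps <- diag(crossprod(C, fo$F %*% C))
      out <- list(E = E, C = C, eps = eps, D = D, converged = TRUE,
                  n_iter = it, nocc = nocc, functional = functional,
                  ints = ints, eri = eri, grid = grid, sys = sys)
      class(out) <- "scf"
      return(out)
    }
    Fd <- diis_extrapolate(diis, fo$F, err)
    if (level_shift > 0) {
      # shift virtual space: F' = F + shift * S (I - D S / 2)-projector
      Q <- S - S %*% D %*% S / 2
      Fd <- Fd + level_shift * Q
    }
    C <- solve_fock(Fd, X)
    D <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
  }
  stop(sprintf("SCF failed to converge in %d iterations (E = %.8f)", max_iter, E))
}

solve_fock <- function(F, X) {
  Fp <- crossprod(X, F %*% X)
  e <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  X %*% e$vectors[, ord, drop = FALSE]
}

gwh_guess <- function(h, S) {
  d <- diag(h)
  K <- 1.75
  F0 <- 0.5 * K * outer(d, d, "+") * S
  diag(F0) <- d
  F0
}

diis_new <- function(max_vec = 8L) {
  e <- new.env()
  e$F <- list(); e$err <- list(); e$max <- max_vec
  e
}

diis_extrapolate <- function(st, F, err) {
  st$F[[length(st$F) + 1L]] <- F
  st$err[[length(st$err) + 1L]] <- err
  if (length(st$F) > st$max) { st$F <- st$F[-1]; st$err <- st$err[-1] }
  n <- length(st$F)
  if (n < 2) return(F)
  B <- matrix(0, n + 1, n + 1)
  for (i in 1:n) for (j in 1:n) B[i, j] <- sum(st$err[[i]] * st$err[[j]])
  B[n + 1, 1:n] <- B[1:n, n + 1] <- -1
  rhs <- c(rep(0, n), -1)
  cf <- tryCatch(solve(B, rhs), error = function(e) NULL)
  if (is.null(cf)) { st$F <- st$F[-1]; st$err <- st$err[-1]; return(F) }
  Fo <- 0 * F
  for (i in 1:n) Fo <- Fo + cf[i] * st$F[[i]]
  Fo
}

#' Unrestricted SCF
#'
#' Spin-unrestricted Hartree-Fock or Kohn-Sham, used for open-shell atoms and
#' as the single-determinant spin-DFT reference in translated-functional
#' consistency checks.
#'
#' @inheritParams scf_rhf
#' @return object of class `scf_u` with alpha/beta orbitals and densities
#' @export
scf_uhf <- function(sys, functional = NULL, grid = NULL, ints = NULL, eri = NULL,
                    max_iter = 300L, conv_grad = 1e-7, level_shift = 0,
                    C0 = NULL, verbose = FALSE) {
  if (is.null(ints)) ints <- core_integrals(sys)
  if (is.null(eri)) eri <- eri_integrals(sys)
  if (!is.null(functional) && is.null(grid)) grid <- build_grid(sys)
  S <- ints$S; h <- ints$hcore
  na_ <- (sys$n_electrons + sys$multiplicity - 1L) %/% 2L
  nb_ <- sys$n_electrons - na_
  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > 1e-8 * max(es$values)
  X <- es$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(es$values[keep]))
  if (is.null(C0)) C0 <- solve_fock(gwh_guess(h, S), X)
  Ca <- Cb <- C0
  Da <- tcrossprod(Ca[, seq_len(na_), drop = FALSE])
  Db <- if (nb_ > 0) tcrossprod(Cb[, seq_len(nb_), drop = FALSE]) else 0 * Da
  diisA <- diis_new(); diisB <- diis_new()
  E <- NA_real_
  for (it in seq_len(max_iter)) {
    if (is.null(functional)) {
      jk <- coulomb_matrix(eri, list(Da, Db), exchange = TRUE)
      Jt <- jk$J[[1]] + jk$J[[2]]
      Fa <- h + Jt - jk$K[[1]]
      Fb <- h + Jt - jk$K[[2]]
      Eel <- sum((Da + Db) * h) + 0.5 * sum((Da + Db) * Jt) -
        0.5 * sum(Da * jk$K[[1]]) - 0.5 * sum(Db * jk$K[[2]])
    } else {
      Js <- coulomb_matrix(eri, list(Da + Db))
      Jt <- Js[[1]]
      xc <- uks_xc(grid, Da, Db, functional)
      Fa <- h + Jt + xc$Va
      Fb <- h + Jt + xc$Vb
      Eel <- sum((Da + Db) * h) + 0.5 * sum((Da + Db) * Jt) + xc$E
    }
    E <- Eel + sys$E_nuc
    erra <- crossprod(X, (Fa %*% Da %*% S - S %*% Da %*% Fa) %*% X)
    errb <- crossprod(X, (Fb %*% Db %*% S - S %*% Db %*% Fb) %*% X)
    gnorm <- max(abs(erra), abs(errb))
    if (verbose) message(sprintf("UHF %3d  E = %.10f  err = %.2e", it, E, gnorm))
    if (gnorm < conv_grad && it > 1) {
      out <- list(E = E, Ca = Ca, Cb = Cb, Da = Da, Db = Db, converged = TRUE,
                  n_iter = it, na = na_, nb = nb_, functional = functional,
                  ints = ints, eri = eri, grid = grid, sys = sys)
      class(out) <- "scf_u"
      return(out)
    }
    Fda <- diis_extrapolate(diisA, Fa, erra)
    Fdb <- diis_extrapolate(diisB, Fb, errb)
    if (level_shift > 0) {
      Fda <- Fda + level_shift * (S - S %*% Da %*% S)
      Fdb <- Fdb + level_shift * (S - S %*% Db %*% S)
    }
    Ca <- solve_fock(Fda, X)
    Cb <- solve_fock(Fdb, X)
    Da <- tcrossprod(Ca[, seq_len(na_), drop = FALSE])
    Db <- if (nb_ > 0) tcrossprod(Cb[, seq_len(nb_), drop = FALSE]) else 0 * Da
  }
  stop("UHF failed to converge")
}

#' @export
print.scf <- function(x, ...) {
  kind <- if (is.null(x$functional)) "RHF" else paste0("RKS(", x$functional, ")")
  cat(sprintf("%s energy: %.10f Ha (%d iterations)\n", kind, x$E, x$n_iter))
  invisible(x)
}
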