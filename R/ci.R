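#' Construct a determinant CI space
#'
#' Alpha/beta string spaces for a CAS with a given M_s sector, with
#' single-excitation tables used by the direct sigma routine.
#'
#' @param n_orb number of active orbitals
#' @param n_el number of active electrons
#' @param ms2 twice the spin projection (n_alpha - n_beta); default 0 for
#'   even electron counts, 1 for odd
#' @return a `ci_space` object
#' @export
ci_space <- function(n_orb, n_el, ms2 = n_el %% 2L) {
  if (n_el < 0 || n_el > 2L * n_orb) stop("impossible electron count for active space")
  na <- (n_el + ms2) / 2; nb <- (n_el - ms2) / 2
  if (na != round(na) || nb < 0) stop("ms2 incompatible with electron count")
  sp <- cpp_ci_space(n_orb, as.integer(na), as.integer(nb))
  sp$dim <- sp$nstra * sp$nstrb
  class(sp) <- "ci_space"
  sp
}

#' @export
print.ci_space <- function(x, ...) {
  cat("CI space: CAS(", x$na + x$nb, ",", x$norb, ") M_s=", (x$na - x$nb) / 2,
      " dim ", x$dim, "\n", sep = "")
  invisible(x)
}

# one-electron integrals folded for the spin-summed sigma:
# h'_tu = h_tu - 1/2 sum_v g_tvvu
fold_h1 <- function(h1, g4) {
  A <- nrow(h1)
  h1p <- h1
  for (t in seq_len(A)) for (u in seq_len(A)) {
    s <- 0
    for (v in seq_len(A)) s <- s + g4[t, v, v, u]
    h1p[t, u] <- h1[t, u] - 0.5 * s
  }
  h1p
}

g4_to_mat <- function(g4) {
  A <- dim(g4)[1]
  matrix(aperm(g4, c(2, 1, 4, 3)), A * A, A * A)
}

#' Sigma vector: H applied to a CI vector
#'
#' H = sum h_tu E_tu + 1/2 sum g_tuvw (E_tu E_vw - delta_uv E_tw), the
#' spin-summed CAS Hamiltonian over active indices (no core constant).
#'
#' @param space a [ci_space()]
#' @param h1 one-electron integrals over active orbitals (A x A)
#' @param g4 two-electron integrals, array `g4[t,u,v,w]` = (tu|vw)-type with
#'   the project 2-DM convention
#' @param C CI vector (length `space$dim` or nstra x nstrb matrix)
#' @return sigma with the same shape as `C`
#' @export
ci_sigma <- function(space, h1, g4, C) {
  vec <- !is.matrix(C)
  if (length(C) != space$dim)
    stop("CI vector does not match the determinant space")
  if (vec) C <- matrix(C, space$nstra, space$nstrb)
  if (nrow(C) != space$nstra || ncol(C) != space$nstrb)
    stop("CI vector does not match the determinant space")
  s <- cpp_sigma(C, fold_h1(h1, g4), g4_to_mat(g4), space)
  if (vec) as.vector(s) else s
}

# dense Hamiltonian matrix (small spaces only; used by Davidson fallback)
ci_dense_h <- function(space, h1, g4) {
  n <- space$dim
  h1p <- fold_h1(h1, g4); g2 <- g4_to_mat(g4)
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- matrix(0, space$nstra, space$nstrb)
    e[j] <- 1
    H[, j] <- as.vector(cpp_sigma(e, h1p, g2, space))
  }
  (H + t(H)) / 2
}

#' Lowest eigenpairs of the CAS Hamiltonian (Davidson)
#'
#' Iterative Davidson diagonalization with diagonal preconditioning; falls
#' back to dense diagonalization for small spaces.
#'
#' @inheritParams ci_sigma
#' @param n_roots number of lowest roots
#' @param tol residual-norm convergence threshold
#' @param guess optional starting vector(s), columns of a matrix
#' @param max_iter maximum subspace expansions
#' @return list with `values` (ascending) and `vectors` (columns)
#' @export
davidson_lowest <- function(space, h1, g4, n_roots = 1L, tol = 1e-9,
                            guess = NULL, max_iter = 200L) {
  n <- space$dim
  if (n_roots > n) stop("more roots requested than the CI dimension")
  if (n <= 400) {
    H <- ci_dense_h(space, h1, g4)
    e <- eigen(H, symmetric = TRUE)
    ord <- order(e$values)[seq_len(n_roots)]
    return(list(values = e$values[ord],
                vectors = matrix(e$vectors[, ord], n, n_roots),
                n_sigma = n, converged = TRUE))
  }
  h1p <- fold_h1(h1, g4); g2 <- g4_to_mat(g4)
  hd <- as.vector(cpp_hdiag(h1p, g2, space))
  sig_of <- function(v) as.vector(cpp_sigma(matrix(v, space$nstra, space$nstrb), h1p, g2, space))
  if (is.null(guess)) {
    guess <- matrix(0, n, n_roots)
    ord <- order(hd)[seq_len(n_roots)]
    guess[cbind(ord, seq_len(n_roots))] <- 1
  }
  V <- qr.Q(qr(guess))
  SV <- matrix(0, n, 0)
  nsig <- 0L
  for (it in seq_len(max_iter)) {
    while (ncol(SV) < ncol(V)) {
      SV <- cbind(SV, sig_of(V[, ncol(SV) + 1L]))
      nsig <- nsig + 1L
    }
    Hs <- crossprod(V, SV)
    Hs <- (Hs + t(Hs)) / 2
    es <- eigen(Hs, symmetric = TRUE)
    ord <- order(es$values)[seq_len(n_roots)]
    theta <- es$values[ord]
    X <- V %*% es$vectors[, ord, drop = FALSE]
    R <- SV %*% es$vectors[, ord, drop = FALSE] - X %*% diag(theta, n_roots)
    rn <- sqrt(colSums(R^2))
    if (all(rn < tol))
      return(list(values = theta, vectors = X, n_sigma = nsig, converged = TRUE))
    # expand with preconditioned residuals
    for (k in which(rn >= tol)) {
      d <- hd - theta[k]
      d[abs(d) < 1e-8] <- 1e-8
      t_ <- R[, k] / d
      t_ <- t_ - V %*% crossprod(V, t_)
      nt <- sqrt(sum(t_^2))
      if (nt > 1e-10) V <- cbind(V, t_ / nt)
    }
    if (ncol(V) > min(n, 20L * n_roots + 20L)) {
      # restart from current best estimates
      V <- qr.Q(qr(X))
      SV <- matrix(0, n, 0)
    }
  }
  stop("Davidson failed to converge; residual norms ",
       paste(signif(rn, 3), collapse = " "))
}

#' Reduced density matrices from CI vectors
#'
#' Spin-summed 1- and 2-RDM with the project convention
#' `Gamma_tuvw = <E_tu E_vw - delta_uv E_tw>`.
#'
#' @param bra,ket CI vectors over the same space (ket defaults to bra)
#' @param space a [ci_space()]
#' @param want2 also compute the 2-RDM
#' @return list with `D` (A x A) and `G` (A^4 array) matrices
#' @export
make_rdms <- function(bra, space, ket = bra, want2 = TRUE) {
  bm <- if (is.matrix(bra)) bra else matrix(bra, space$nstra, space$nstrb)
  km <- if (is.matrix(ket)) ket else matrix(ket, space$nstra, space$nstrb)
  if (length(bm) != space$dim || length(km) != space$dim)
    stop("CI vector does not match the determinant space")
  identical_vecs <- identical(bra, ket)
  r <- cpp_rdm12(bm, if (identical_vecs) bm else km, space, want2)
  r
}
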