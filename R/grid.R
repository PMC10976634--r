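#' Build a molecular quadrature grid
#'
#' Atom-centered quadrature: Mura-Knowles log-3 radial grids combined with a
#' Gauss-Legendre (theta) x uniform (phi) angular product rule, pruned near
#' the nucleus, with Becke fuzzy-cell weights (three smoothing passes,
#' Bragg-radius size adjustment). Points are stored in batches; AO amplitudes
#' on the grid are computed per batch and memoised.
#'
#' @param sys a `qc_system`
#' @param level integer grid level 1-5 (default 3); higher is finer
#' @param batch_size points per batch
#' @return object of class `qc_grid` with `points` (Bohr), `w` (weights)
#' @export
build_grid <- function(sys, level = 3L, batch_size = 8000L) {
  if (length(sys$atoms) < 1) stop("empty molecule")
  if (level < 1 || level > 6) stop("grid level out of supported range")
  n_rad <- c(35L, 50L, 65L, 80L, 95L, 110L)[level]
  n_th <- c(9L, 11L, 15L, 19L, 23L, 27L)[level]
  natom <- length(sys$atoms)
  rb <- .bragg[sys$Z] / .bohr
  pts <- list(); wts <- list(); patom <- list()
  for (ia in seq_len(natom)) {
    alpha <- if (sys$Z[ia] %in% c(3, 4, 11, 12, 19, 20)) 7.0 else 5.0
    x <- (seq_len(n_rad) - 0.5) / n_rad
    r <- -alpha * log1p(-x^3)
    drdx <- alpha * 3 * x^2 / (1 - x^3)
    wrad <- drdx / n_rad * r^2
    for (k in seq_len(n_rad)) {
      nt <- if (r[k] < 0.2 * rb[ia]) max(5L, n_th %/% 3L)
            else if (r[k] < 0.5 * rb[ia] || r[k] > 12) max(7L, (2L * n_th) %/% 3L)
            else n_th
      ang <- angular_mesh(nt)
      p <- sweep(r[k] * ang$xyz, 2, sys$xyz[ia, ], "+")
      pts[[length(pts) + 1L]] <- p
      wts[[length(wts) + 1L]] <- wrad[k] * ang$w
      patom[[length(patom) + 1L]] <- rep(ia, nrow(p))
    }
  }
  points <- do.call(rbind, pts)
  w <- unlist(wts)
  pa <- unlist(patom)
  wb <- becke_weights(points, sys$xyz, rb, pa)
  keep <- w * wb > 1e-14
  points <- points[keep, , drop = FALSE]
  w <- (w * wb)[keep]
  n <- length(w)
  starts <- seq(1L, n, by = batch_size)
  batches <- lapply(starts, function(s) s:min(s + batch_size - 1L, n))
  g <- list(points = points, w = w, batches = batches, level = level,
            shells = sys$shells, n_ao = sys$n_ao, cache = new.env(parent = emptyenv()))
  class(g) <- "qc_grid"
  g
}

#' @export
print.qc_grid <- function(x, ...) {
  cat("Molecular grid: ", length(x$w), " points (level ", x$level, ", ",
      length(x$batches), " batches)\n", sep = "")
  invisible(x)
}

# unit-sphere product mesh exact for spherical harmonics up to degree
# 2*n_th - 1 (Gauss-Legendre in cos(theta), trapezoid in phi)
angular_mesh <- function(n_th) {
  gl <- gauss_legendre(n_th)
  n_ph <- 2L * n_th
  phi <- 2 * pi * (seq_len(n_ph) - 1L) / n_ph
  ct <- gl$x; st <- sqrt(pmax(0, 1 - ct^2))
  xyz <- cbind(as.vector(outer(st, cos(phi))),
               as.vector(outer(st, sin(phi))),
               rep(ct, times = n_ph))
  w <- rep(gl$w, times = n_ph) * (2 * pi / n_ph)
  list(xyz = xyz, w = w)
}

gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

becke_weights <- function(points, centers, radii, point_atom) {
  natom <- nrow(centers)
  if (natom == 1) return(rep(1, nrow(points)))
  n <- nrow(points)
  d <- matrix(0, n, natom)
  for (a in seq_len(natom))
    d[, a] <- sqrt((points[, 1] - centers[a, 1])^2 + (points[, 2] - centers[a, 2])^2 +
                   (points[, 3] - centers[a, 3])^2)
  P <- matrix(1, n, natom)
  f3 <- function(m) { for (k in 1:3) m <- 1.5 * m - 0.5 * m^3; m }
  for (a in seq_len(natom)) for (b in seq_len(natom)) {
    if (a == b) next
    Rab <- sqrt(sum((centers[a, ] - centers[b, ])^2))
    mu <- (d[, a] - d[, b]) / Rab
    chi <- radii[a] / radii[b]
    u <- (chi - 1) / (chi + 1)
    aa <- max(min(u / (u^2 - 1), 0.45), -0.45)
    mu <- mu + aa * (1 - mu^2)
    P[, a] <- P[, a] * 0.5 * (1 - f3(mu))
  }
  tot <- rowSums(P)
  P[cbind(seq_len(n), point_atom)] / pmax(tot, 1e-300)
}

# AO amplitudes (and gradients) for one batch, memoised on the grid object
ao_block <- function(grid, ib, deriv = TRUE) {
  key <- paste0("b", ib, if (deriv) "d" else "v")
  got <- grid$cache[[key]]
  if (!is.null(got)) return(got)
  idx <- grid$batches[[ib]]
  v <- cpp_ao_grid(grid$shells$l, grid$shells$centers, grid$shells$exps,
                   grid$shells$coefs, grid$points[idx, , drop = FALSE], deriv)
  grid$cache[[key]] <- v
  v
}

clear_ao_cache <- function(grid) {
  rm(list = ls(grid$cache), envir = grid$cache)
  invisible(grid)
}

.fun_code <- function(functional) {
  switch(tolower(functional), lda = 0L, pbe = 1L, blyp = 2L,
         stop("unknown functional: ", functional))
}

# restricted KS exchange-correlation: energy and AO-basis potential matrix
ks_xc <- function(grid, D, functional) {
  code <- .fun_code(functional)
  gga <- code != 0L
  nao <- grid$n_ao
  V <- matrix(0, nao, nao)
  E <- 0
  for (ib in seq_along(grid$batches)) {
    idx <- grid$batches[[ib]]
    ao <- ao_block(grid, ib, deriv = TRUE)
    Phi <- ao$val
    PD <- Phi %*% D
    rho <- rowSums(PD * Phi)
    gx <- 2 * rowSums(PD * ao$dx); gy <- 2 * rowSums(PD * ao$dy); gz <- 2 * rowSums(PD * ao$dz)
    sig <- gx^2 + gy^2 + gz^2
    live <- rho > 1e-12
    if (!any(live)) next
    r2 <- pmax(rho, 1e-12)
    k <- cpp_xc_spin(code, r2 / 2, r2 / 2, sig / 4, sig / 4, sig / 4)
    w <- grid$w[idx] * live
    E <- E + sum(w * k$exc)
    vr <- 0.5 * (k$vra + k$vrb) * w
    B <- vr * Phi
    if (gga) {
      vs <- 0.25 * (k$vsaa + k$vsab + k$vsbb) * w
      Cm <- 2 * (vs * gx * ao$dx + vs * gy * ao$dy + vs * gz * ao$dz)
      V <- V + crossprod(Phi, B + Cm) + crossprod(Cm, Phi)
    } else {
      V <- V + crossprod(Phi, B)
    }
  }
  list(E = E, V = (V + t(V)) / 2)
}

# unrestricted KS exchange-correlation
uks_xc <- function(grid, Da, Db, functional) {
  code <- .fun_code(functional)
  gga <- code != 0L
  nao <- grid$n_ao
  Va <- matrix(0, nao, nao); Vb <- matrix(0, nao, nao)
  E <- 0
  for (ib in seq_along(grid$batches)) {
    idx <- grid$batches[[ib]]
    ao <- ao_block(grid, ib, deriv = TRUE)
    Phi <- ao$val
    PDa <- Phi %*% Da; PDb <- Phi %*% Db
    ra <- rowSums(PDa * Phi); rb <- rowSums(PDb * Phi)
    gax <- 2 * rowSums(PDa * ao$dx); gay <- 2 * rowSums(PDa * ao$dy); gaz <- 2 * rowSums(PDa * ao$dz)
    gbx <- 2 * rowSums(PDb * ao$dx); gby <- 2 * rowSums(PDb * ao$dy); gbz <- 2 * rowSums(PDb * ao$dz)
    live <- (ra + rb) > 1e-12
    if (!any(live)) next
    k <- cpp_xc_spin(code, pmax(ra, 0), pmax(rb, 0),
                     gax^2 + gay^2 + gaz^2,
                     gax * gbx + gay * gby + gaz * gbz,
                     gbx^2 + gby^2 + gbz^2)
    w <- grid$w[idx] * live
    E <- E + sum(w * k$exc)
    Ba <- (k$vra * w) * Phi
    Bb <- (k$vrb * w) * Phi
    if (gga) {
      wsaa <- k$vsaa * w; wsab <- k$vsab * w; wsbb <- k$vsbb * w
      Ca <- (2 * wsaa * gax + wsab * gbx) * ao$dx + (2 * wsaa * gay + wsab * gby) * ao$dy +
            (2 * wsaa * gaz + wsab * gbz) * ao$dz
      Cb <- (2 * wsbb * gbx + wsab * gax) * ao$dx + (2 * wsbb * gby + wsab * gay) * ao$dy +
            (2 * wsbb * gbz + wsab * gaz) * ao$dz
      Va <- Va + crossprod(Phi, Ba + Ca) + crossprod(Ca, Phi)
      Vb <- Vb + crossprod(Phi, Bb + Cb) + crossprod(Cb, Phi)
    } else {
      Va <- Va + crossprod(Phi, Ba)
      Vb <- Vb + crossprod(Phi, Bb)
    }
  }
  list(E = E, Va = (Va + t(Va)) / 2, Vb = (Vb + t(Vb)) / 2)
}
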