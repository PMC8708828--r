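# Finite-difference linearized Poisson-Boltzmann polar solvation.
#
# The molecular interior (union of atom spheres) takes eps_in, the exterior
# eps_out; face dielectrics are harmonic means of three samples along each
# grid edge, which smooths the dielectric boundary and gives near-quadratic
# convergence on the Born ion. Charges are spread to the eight surrounding
# nodes trilinearly, the potential is read back with the same trilinear
# weights, and the polar solvation energy is the difference between the
# solvated solve and a uniform-eps_in reference solve on the identical
# grid, which cancels the grid self-energy. Linear system solved matrix-free
# by conjugate gradients with an analytic Coulomb/Debye-Hueckel Dirichlet
# boundary.

#' Poisson-Boltzmann grid settings
#'
#' @param spacing grid spacing h (Angstrom).
#' @param eps_in solute interior dielectric (default 2.0).
#' @param eps_out solvent dielectric (default 78.54).
#' @param ionic_strength monovalent ionic strength (mol/L, default 0 =
#'   plain Poisson).
#' @param margin clearance between any atom and the grid faces (Angstrom,
#'   >= 6 enforced at solve time; default 8).
#' @param tol relative residual tolerance of the CG solve.
#' @param max_iter CG iteration cap.
#' @return object of class `PbGrid`.
#' @export
pb_grid <- function(spacing = 0.5, eps_in = 2.0, eps_out = 78.54,
                    ionic_strength = 0, margin = 8, tol = 1e-6,
                    max_iter = 10000L) {
  if (spacing <= 0) stop("grid spacing must be positive")
  if (!(eps_out >= eps_in && eps_in >= 1))
    stop("need eps_out >= eps_in >= 1")
  if (margin < 6) stop("grid margin must be at least 6 Angstrom")
  structure(list(spacing = spacing, eps_in = eps_in, eps_out = eps_out,
                 ionic_strength = ionic_strength, margin = margin,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "PbGrid")
}

# Debye screening: kappa^2 [A^-2] for monovalent I [mol/L] at 298.15 K.
# 8*pi*ke/(RT) * N_A * 1e-27 = 8.481 per (mol/L); divided by eps_out in the
# linearized PB term eps_out * kappa_bar^2.
pb_kappa2 <- function(ionic_strength, eps_out) {
  if (ionic_strength <= 0) return(0)
  8.4806 * ionic_strength / eps_out
}

#' Polar solvation energy by finite-difference linearized PB
#'
#' @param frame n x 3 coordinate matrix of the charged atoms.
#' @param charges per-atom charges (e).
#' @param radii per-atom dielectric cavity radii (Angstrom).
#' @param grid a [pb_grid()].
#' @return polar solvation free energy (kJ/mol).
#' @export
pb_solve <- function(frame, charges, radii, grid = pb_grid()) {
  frame <- rbind(frame)
  if (length(charges) != nrow(frame) || length(radii) != nrow(frame))
    stop("charges/radii length mismatch")
  if (all(charges == 0)) return(0)
  h <- grid$spacing
  lo <- apply(frame, 2, min) - grid$margin
  hi <- apply(frame, 2, max) + grid$margin
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  gx <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 1) * h)
  # margin pre-check (atoms must sit >= 6 A inside every face)
  for (k in 1:3)
    if (min(frame[, k]) - lo[k] < 6 || max(gx[[k]]) - max(frame[, k]) < 6)
      stop("atom within 6 Angstrom of the grid boundary")

  rho <- pb_spread_charges(frame, charges, lo, h, dims)
  solv <- pb_solve_one(frame, charges, radii, grid$eps_in, grid$eps_out,
                       pb_kappa2(grid$ionic_strength, grid$eps_out),
                       lo, h, dims, gx, rho, grid$tol, grid$max_iter)
  ref <- pb_solve_one(frame, charges, radii, grid$eps_in, grid$eps_in, 0,
                      lo, h, dims, gx, rho, grid$tol, grid$max_iter)
  phi_s <- pb_interp(solv, frame, lo, h)
  phi_r <- pb_interp(ref, frame, lo, h)
  0.5 * KE_COULOMB * sum(charges * (phi_s - phi_r))
}

pb_spread_charges <- function(frame, charges, lo, h, dims) {
  rho <- array(0, dim = dims)
  for (a in seq_len(nrow(frame))) {
    fi <- (frame[a, ] - lo) / h + 1
    i0 <- floor(fi); fr <- fi - i0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fr[1] else 1 - fr[1]) *
           (if (dy) fr[2] else 1 - fr[2]) *
           (if (dz) fr[3] else 1 - fr[3])
      rho[i0[1] + dx, i0[2] + dy, i0[3] + dz] <-
        rho[i0[1] + dx, i0[2] + dy, i0[3] + dz] + w * charges[a]
    }
  }
  rho
}

pb_interp <- function(phi, frame, lo, h) {
  vapply(seq_len(nrow(frame)), function(a) {
    fi <- (frame[a, ] - lo) / h + 1
    i0 <- floor(fi); fr <- fi - i0
    s <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fr[1] else 1 - fr[1]) *
           (if (dy) fr[2] else 1 - fr[2]) *
           (if (dz) fr[3] else 1 - fr[3])
      s <- s + w * phi[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    s
  }, numeric(1))
}

# eps at arbitrary points: eps_in inside any atom sphere, eps_out outside
pb_eps_at <- function(px, py, pz, frame, radii, ei, eo) {
  inside <- rep(FALSE, length(px))
  for (a in seq_len(nrow(frame))) {
    d2 <- (px - frame[a, 1])^2 + (py - frame[a, 2])^2 + (pz - frame[a, 3])^2
    inside <- inside | (d2 < radii[a]^2)
  }
  ifelse(inside, ei, eo)
}

pb_face_eps <- function(axis, frame, radii, ei, eo, gx, h, dims) {
  dd <- dims; dd[axis] <- dd[axis] - 1L
  idx <- as.matrix(expand.grid(seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3])))
  p0 <- cbind(gx[[1]][idx[, 1]], gx[[2]][idx[, 2]], gx[[3]][idx[, 3]])
  inv <- 0
  for (t in c(0.25, 0.5, 0.75)) {
    pm <- p0
    pm[, axis] <- pm[, axis] + t * h
    inv <- inv + 1 / pb_eps_at(pm[, 1], pm[, 2], pm[, 3], frame, radii, ei, eo)
  }
  array(3 / inv, dim = dd)
}

pb_solve_one <- function(frame, charges, radii, ei, eo, kappa2,
                         lo, h, dims, gx, rho, tol, max_iter) {
  if (ei == eo) {
    ex <- array(ei, dim = dims - c(1L, 0L, 0L))
    ey <- array(ei, dim = dims - c(0L, 1L, 0L))
    ez <- array(ei, dim = dims - c(0L, 0L, 1L))
  } else {
    ex <- pb_face_eps(1, frame, radii, ei, eo, gx, h, dims)
    ey <- pb_face_eps(2, frame, radii, ei, eo, gx, h, dims)
    ez <- pb_face_eps(3, frame, radii, ei, eo, gx, h, dims)
  }
  # screening term only where the solvent dielectric applies
  diag_k <- if (kappa2 > 0) {
    idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                                 seq_len(dims[3])))
    p <- cbind(gx[[1]][idx[, 1]], gx[[2]][idx[, 2]], gx[[3]][idx[, 3]])
    epsn <- pb_eps_at(p[, 1], p[, 2], p[, 3], frame, radii, ei, eo)
    array((epsn == eo) * eo * kappa2 * h^2, dim = dims)
  } else 0

  bmask <- array(FALSE, dim = dims)
  bmask[c(1, dims[1]), , ] <- TRUE
  bmask[, c(1, dims[2]), ] <- TRUE
  bmask[, , c(1, dims[3])] <- TRUE
  bidx <- which(bmask)
  ai <- arrayInd(bidx, dims)
  bx <- gx[[1]][ai[, 1]]; by <- gx[[2]][ai[, 2]]; bz <- gx[[3]][ai[, 3]]
  kap <- sqrt(kappa2)
  phib <- 0
  for (a in seq_len(nrow(frame))) {
    r <- pmax(sqrt((bx - frame[a, 1])^2 + (by - frame[a, 2])^2 +
                   (bz - frame[a, 3])^2), 1e-6)
    scr <- if (kap > 0) exp(-kap * r) else 1
    phib <- phib + charges[a] * scr / (eo * r)
  }
  phi <- array(0, dim = dims)
  phi[bidx] <- phib

  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  apply_A <- function(p) {
    out <- -diag_k * p
    dfx <- ex * (p[2:n1, , ] - p[1:(n1 - 1), , ])
    out[1:(n1 - 1), , ] <- out[1:(n1 - 1), , ] + dfx
    out[2:n1, , ] <- out[2:n1, , ] - dfx
    dfy <- ey * (p[, 2:n2, ] - p[, 1:(n2 - 1), ])
    out[, 1:(n2 - 1), ] <- out[, 1:(n2 - 1), ] + dfy
    out[, 2:n2, ] <- out[, 2:n2, ] - dfy
    dfz <- ez * (p[, , 2:n3] - p[, , 1:(n3 - 1)])
    out[, , 1:(n3 - 1)] <- out[, , 1:(n3 - 1)] + dfz
    out[, , 2:n3] <- out[, , 2:n3] - dfz
    out
  }
  # solve (-A) x = -rhs (SPD) with boundary nodes held at the analytic value
  rhs <- -4 * pi * rho / h
  x <- phi
  r <- rhs - apply_A(x)
  r[bidx] <- 0
  p <- r
  rs <- sum(r * r)
  rs0 <- max(rs, 1e-300)
  res <- sqrt(rs / rs0)
  for (it in seq_len(max_iter)) {
    Ap <- apply_A(p)
    Ap[bidx] <- 0
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    res <- sqrt(rs_new / rs0)
    if (res < tol) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (res >= tol)
    stop("PB solver did not converge in ", max_iter,
         " iterations (relative residual ", signif(res, 3), ")")
  x
}
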