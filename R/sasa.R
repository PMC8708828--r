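# Shrake-Rupley solvent-accessible surface area with a deterministic
# golden-spiral point set (no RNG).

#' Deterministic unit-sphere point set (golden spiral)
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (i - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere of radius `r_i + probe` is sampled with a fixed
#' golden-spiral point set; points inside any neighbor's expanded sphere are
#' occluded. Per-atom accessible area = accessible fraction times
#' `4 pi (r_i + probe)^2`.
#'
#' @param frame n x 3 coordinate matrix.
#' @param radii per-atom radii (Angstrom, > 0).
#' @param probe probe radius (Angstrom, default 1.4).
#' @param n_points sample points per atom (>= 92, default 960).
#' @return object of class `SasaResult`: list with `total`, `per_atom`
#'   (Angstrom^2) and `probe_radius`.
#' @export
sasa <- function(frame, radii, probe = 1.4, n_points = 960) {
  n <- nrow(frame)
  if (length(radii) != n) stop("radii length does not match atom count")
  if (any(radii <= 0)) stop("radii must be positive")
  if (n_points < 92) stop("need at least 92 sample points")
  pts <- sphere_points(n_points)
  expand <- radii + probe
  per_atom <- numeric(n)
  d2 <- cross_dist2(frame, frame)
  for (i in seq_len(n)) {
    thresh <- (expand[i] + expand)^2
    nb <- which(d2[i, ] < thresh & seq_len(n) != i)
    if (length(nb) == 0L) {
      per_atom[i] <- 4 * pi * expand[i]^2
      next
    }
    p <- sweep(pts * expand[i], 2, frame[i, ], `+`)
    occluded <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - frame[j, 1])^2 + (p[, 2] - frame[j, 2])^2 +
             (p[, 3] - frame[j, 3])^2
      occluded <- occluded | (dj2 < expand[j]^2)
      if (all(occluded)) break
    }
    per_atom[i] <- 4 * pi * expand[i]^2 * sum(!occluded) / n_points
  }
  structure(list(total = sum(per_atom), per_atom = per_atom,
                 probe_radius = probe),
            class = "SasaResult")
}

#' @export
print.SasaResult <- function(x, ...) {
  cat(sprintf("SASA: %.2f A^2 over %d atoms (probe %.2f A)\n",
              x$total, length(x$per_atom), x$probe_radius))
  invisible(x)
}
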