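# Rigid-body insertion of a protein into an implicit hydrophobic slab.
#
# The transfer free energy of a pose is an ASA-weighted sum
#   dG_transfer = sum_atoms sigma(residue) * ASA_atom * f(z_atom)
# with f = 1 inside the slab core (|z| <= half_width), 0 outside
# (|z| >= half_width + smoothing) and a linear ramp between. sigma is a
# per-residue transfer coefficient (kJ mol^-1 A^-2) from a shipped
# hydrophobicity scale: negative for apolar residues (insertion favorable),
# positive for polar/charged ones. This is a deliberately simplified
# implicit-membrane energy; depths and angles it reports are qualitative.
# The optimizer is an exhaustive, deterministic grid search over depth,
# tilt and azimuth; per-atom ASA is computed once on the isolated protein
# (it is pose-independent for a rigid body).

#' Implicit hydrophobic slab model
#'
#' @param half_width hydrophobic half-thickness (Angstrom, default 15).
#' @param interface_smoothing linear ramp width at the interface (Angstrom,
#'   default 3).
#' @param scale per-residue transfer coefficients: data frame with columns
#'   `residue` and `sigma` (kJ mol^-1 A^-2). Default: the shipped scale
#'   (see [hydrophobicity_scale()]).
#' @return list of class `SlabModel`.
#' @export
slab_model <- function(half_width = 15, interface_smoothing = 3,
                       scale = NULL) {
  if (half_width <= 0) stop("half width must be positive")
  if (interface_smoothing < 0) stop("smoothing must be non-negative")
  if (is.null(scale)) scale <- hydrophobicity_scale()
  structure(list(half_width = half_width,
                 interface_smoothing = interface_smoothing,
                 scale = scale),
            class = "SlabModel")
}

#' Shipped residue-level hydrophobicity scale
#'
#' Per-residue membrane-transfer coefficients (kJ mol^-1 A^-2): side-chain
#' water-to-octanol transfer free energies in the Wimley-White spirit
#' divided by a reference exposed residue area, so that
#' sigma * exposed-ASA approximates the residue's transfer free energy.
#' Includes the coarse fixture bead types `HPB` (apolar) and `PLB` (polar).
#'
#' @return data frame with columns `residue`, `sigma`.
#' @export
hydrophobicity_scale <- function() {
  path <- system.file("extdata", "hydrophobicity_scale.tsv",
                      package = "memscan")
  utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
}

slab_f <- function(z, hw, sm) {
  az <- abs(z)
  if (sm <= 0) return(as.numeric(az <= hw))
  pmin(1, pmax(0, (hw + sm - az) / sm))
}

# per-atom sigma * ASA weights for a selection, on the isolated protein
slab_weights <- function(frame, system, slab, selection, probe = 1.4,
                         n_points = 240) {
  idx <- resolve_selection(system, selection)
  resn <- system$atoms$resname[idx]
  hit <- match(resn, slab$scale$residue)
  if (anyNA(hit))
    stop("no transfer coefficient for residue type(s): ",
         paste(unique(resn[is.na(hit)]), collapse = ", "))
  sig <- slab$scale$sigma[hit]
  asa <- sasa(frame[idx, , drop = FALSE], atom_radii(system, idx), probe,
              n_points)$per_atom
  list(idx = idx, w = sig * asa)
}

# z coordinates of centered coords under pose (depth, tilt, azimuth):
# rotate about the centroid by Rz(azimuth) then Rx(tilt), translate by depth
pose_z <- function(centered, tilt_deg, azimuth_deg) {
  R <- rot_x(tilt_deg * pi / 180) %*% rot_z(azimuth_deg * pi / 180)
  as.numeric(centered %*% R[3, ])
}

#' Transfer free energy of one rigid pose
#'
#' @param frame n x 3 coordinate matrix of the whole system.
#' @param system the `MolecularSystem`.
#' @param slab a [slab_model()].
#' @param pose numeric `c(depth, tilt, azimuth)`: Z translation of the
#'   selection centroid (Angstrom) and rotation angles (degrees) applied as
#'   azimuth about Z then tilt about X, both about the centroid.
#' @param selection protein selection (default all atoms).
#' @param weights optional precomputed result of the internal ASA weighting
#'   (reused across poses by the optimizer).
#' @return dG_transfer (kJ/mol).
#' @export
transfer_energy <- function(frame, system, slab, pose, selection = "all",
                            weights = NULL) {
  if (any(!is.finite(pose))) stop("pose must be finite")
  if (is.null(weights))
    weights <- slab_weights(frame, system, slab, selection)
  ctr <- colMeans(frame[weights$idx, , drop = FALSE])
  centered <- sweep(frame[weights$idx, , drop = FALSE], 2, ctr)
  z <- pose_z(centered, pose[2], pose[3]) + pose[1]
  sum(weights$w * slab_f(z, slab$half_width, slab$interface_smoothing))
}

#' Optimal rigid-body insertion by exhaustive grid search
#'
#' Scans depth x tilt x azimuth, returns the global grid minimum of the
#' transfer energy. Ties are broken deterministically towards the smallest
#' azimuth, then tilt, then depth. The reported angle is between the
#' selection's first principal axis of inertia (equal atom weights) and
#' the slab plane, in `[0, 90]` degrees.
#'
#' @param frame n x 3 coordinate matrix.
#' @param system the `MolecularSystem`.
#' @param slab a [slab_model()].
#' @param depth_step depth grid step (Angstrom, default 0.2).
#' @param tilt_step tilt grid step (degrees, default 2; tilt spans 0-180).
#' @param azimuth_step azimuth grid step (degrees, default 30; spans
#'   0-360).
#' @param selection protein selection (default all atoms).
#' @return object of class `InsertionResult`: `angle` (degrees), `depth`,
#'   `tilt`, `azimuth`, `dg_transfer` (kJ/mol), `contacting_residues`,
#'   `outside_residues`.
#' @export
optimize_insertion <- function(frame, system, slab, depth_step = 0.2,
                               tilt_step = 2, azimuth_step = 30,
                               selection = "all") {
  if (depth_step <= 0 || tilt_step <= 0 || azimuth_step <= 0)
    stop("grid steps must be positive")
  weights <- slab_weights(frame, system, slab, selection)
  idx <- weights$idx
  ctr <- colMeans(frame[idx, , drop = FALSE])
  centered <- sweep(frame[idx, , drop = FALSE], 2, ctr)
  maxr <- sqrt(max(rowSums(centered^2)))
  dmax <- slab$half_width + slab$interface_smoothing + maxr + depth_step
  depths <- seq(-dmax, dmax, by = depth_step)
  tilts <- seq(0, 180, by = tilt_step)
  azimuths <- seq(0, 360 - azimuth_step, by = azimuth_step)
  best <- list(dg = Inf, depth = NA, tilt = NA, azimuth = NA)
  hw <- slab$half_width; sm <- slab$interface_smoothing
  for (az in azimuths) {
    for (ti in tilts) {
      z0 <- pose_z(centered, ti, az)
      zmat <- outer(z0, depths, `+`)
      fmat <- if (sm > 0) pmin(pmax((hw + sm - abs(zmat)) / sm, 0), 1)
              else (abs(zmat) <= hw) * 1
      dg <- as.numeric(crossprod(weights$w, fmat))
      k <- which.min(dg)
      if (dg[k] < best$dg) {
        best <- list(dg = dg[k], depth = depths[k], tilt = ti, azimuth = az)
      }
    }
  }
  if (!is.finite(best$dg)) stop("empty pose grid")
  # never report a positive optimum: the fully-withdrawn pose has dG = 0
  if (best$dg > 0) {
    best <- list(dg = 0, depth = dmax, tilt = 0, azimuth = 0)
  }
  zopt <- pose_z(centered, best$tilt, best$azimuth) + best$depth
  fopt <- slab_f(zopt, hw, sm)
  resid <- system$atoms$resid[idx]
  contacting <- sort(unique(resid[fopt > 0]))
  outside <- sort(unique(setdiff(resid, contacting)))
  # first principal axis of the posed coordinates vs the slab plane
  R <- rot_x(best$tilt * pi / 180) %*% rot_z(best$azimuth * pi / 180)
  posed <- centered %*% t(R)
  ev <- eigen(crossprod(posed) / nrow(posed), symmetric = TRUE)
  axis1 <- ev$vectors[, 1]
  angle <- asin(pmin(1, abs(axis1[3]))) * 180 / pi
  structure(list(angle = angle, depth = best$depth, tilt = best$tilt,
                 azimuth = best$azimuth, dg_transfer = best$dg,
                 contacting_residues = contacting,
                 outside_residues = outside),
            class = "InsertionResult")
}

#' @export
print.InsertionResult <- function(x, ...) {
  cat(sprintf(
    "Slab insertion optimum: dG_transfer %.2f kJ/mol at depth %.1f A, tilt %g deg (axis angle %.1f deg)\n",
    x$dg_transfer, x$depth, x$tilt, x$angle))
  cat("  residues in slab:", length(x$contacting_residues),
      "| outside:", length(x$outside_residues), "\n")
  invisible(x)
}
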