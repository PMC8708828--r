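# Protein-membrane interface analysis: buried contact surface area,
# geometric hydrogen-bond detection over time, contacting-residue lists.

#' Hydrogen-bond geometric criteria
#'
#' Defaults (3.5 Angstrom heavy-atom donor-acceptor distance, 150 degree
#' D-H...A angle) follow common MD-analysis practice; both are free
#' parameters.
#'
#' @param heavy_distance_max maximum D...A heavy-atom distance (Angstrom).
#' @param angle_min minimum D-H...A angle at the hydrogen (degrees).
#' @return list of class `HbondCriteria`.
#' @export
hbond_criteria <- function(heavy_distance_max = 3.5, angle_min = 150) {
  if (heavy_distance_max <= 0) stop("distance cutoff must be positive")
  if (angle_min <= 0 || angle_min > 180) stop("angle must be in (0, 180]")
  structure(list(heavy_distance_max = heavy_distance_max,
                 angle_min = angle_min),
            class = "HbondCriteria")
}

#' Protein-membrane contact surface area
#'
#' Buried interface area `SASA(P) + SASA(M) - SASA(P union M)`, i.e. the
#' total buried surface summed over both sides of the interface (the
#' convention whose magnitude matches a two-helix membrane footprint).
#' `single_sided = TRUE` halves it.
#'
#' @param frame n x 3 coordinate matrix.
#' @param system the `MolecularSystem` (for radii).
#' @param set_p,set_m disjoint atom selections.
#' @param probe probe radius (Angstrom).
#' @param n_points SASA sample points per atom.
#' @param single_sided divide the buried area by two.
#' @return contact area (Angstrom^2, >= 0).
#' @export
contact_surface_area <- function(frame, system, set_p, set_m, probe = 1.4,
                                 n_points = 240, single_sided = FALSE) {
  ip <- resolve_selection(system, set_p)
  im <- resolve_selection(system, set_m)
  if (length(intersect(ip, im))) stop("contact sets overlap")
  rp <- atom_radii(system, ip)
  rm_ <- atom_radii(system, im)
  s_p <- sasa(frame[ip, , drop = FALSE], rp, probe, n_points)$total
  s_m <- sasa(frame[im, , drop = FALSE], rm_, probe, n_points)$total
  s_pm <- sasa(frame[c(ip, im), , drop = FALSE], c(rp, rm_), probe,
               n_points)$total
  buried <- max(s_p + s_m - s_pm, 0)
  if (single_sided) buried / 2 else buried
}

#' Contact surface area time series
#'
#' @param traj a `Trajectory`.
#' @param set_p,set_m disjoint atom selections.
#' @inheritParams contact_surface_area
#' @return object of class `ContactReport`: data frame `time`, `area` with
#'   a `summary` attribute.
#' @export
contact_area_series <- function(traj, set_p, set_m, probe = 1.4,
                                n_points = 240, single_sided = FALSE) {
  a <- vapply(seq_len(n_frames(traj)), function(f)
    contact_surface_area(frame_coords(traj, f), traj$system, set_p, set_m,
                         probe, n_points, single_sided), numeric(1))
  res <- data.frame(time = traj$times, area = a)
  class(res) <- c("ContactReport", "data.frame")
  attr(res, "summary") <- rbind(area = mean_sd(a))
  res
}

#' @export
print.ContactReport <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Contact surface area over %d frames: %.2f (+/- %.2f) A^2\n",
              nrow(x), s["area", 1], s["area", 2]))
  invisible(x)
}

#' Geometric hydrogen bonds over a trajectory
#'
#' A bond is counted when the heavy donor-acceptor distance is at most the
#' cutoff and the D-H...A angle at the hydrogen is at least the minimum.
#'
#' @param traj a `Trajectory`.
#' @param donors two-column integer matrix of (donor heavy atom, hydrogen)
#'   index pairs.
#' @param acceptors integer indices of acceptor heavy atoms.
#' @param criteria a [hbond_criteria()].
#' @return list of class `HbondSeries`: `per_frame` (list of data frames
#'   with columns `donor`, `hydrogen`, `acceptor`, `distance`, `angle`),
#'   `counts` (integer per frame) and `mean_count`.
#' @export
hydrogen_bonds <- function(traj, donors, acceptors,
                           criteria = hbond_criteria()) {
  donors <- rbind(donors)
  if (nrow(donors) == 0L) stop("empty donor set")
  if (length(acceptors) == 0L) stop("empty acceptor set")
  per_frame <- vector("list", n_frames(traj))
  counts <- integer(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, f)
    D <- fr[donors[, 1], , drop = FALSE]
    H <- fr[donors[, 2], , drop = FALSE]
    A <- fr[acceptors, , drop = FALSE]
    dda <- cross_dist(D, A)
    hits <- which(dda <= criteria$heavy_distance_max, arr.ind = TRUE)
    # exclude self-pairs (acceptor == donor heavy atom)
    if (nrow(hits)) {
      keep <- donors[hits[, 1], 1] != acceptors[hits[, 2]]
      hits <- hits[keep, , drop = FALSE]
    }
    if (nrow(hits)) {
      hd <- D[hits[, 1], , drop = FALSE] - H[hits[, 1], , drop = FALSE]
      ha <- A[hits[, 2], , drop = FALSE] - H[hits[, 1], , drop = FALSE]
      cosang <- rowSums(hd * ha) /
        (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      ok <- ang >= criteria$angle_min
      per_frame[[f]] <- data.frame(
        donor = donors[hits[ok, 1], 1],
        hydrogen = donors[hits[ok, 1], 2],
        acceptor = acceptors[hits[ok, 2]],
        distance = dda[hits[ok, , drop = FALSE]],
        angle = ang[ok])
    } else {
      per_frame[[f]] <- data.frame(donor = integer(0), hydrogen = integer(0),
                                   acceptor = integer(0),
                                   distance = numeric(0), angle = numeric(0))
    }
    counts[f] <- nrow(per_frame[[f]])
  }
  structure(list(per_frame = per_frame, counts = counts,
                 mean_count = mean(counts), times = traj$times),
            class = "HbondSeries")
}

#' @export
print.HbondSeries <- function(x, ...) {
  cat(sprintf("Hydrogen bonds over %d frames: mean %.2f (range %d-%d)\n",
              length(x$counts), x$mean_count, min(x$counts), max(x$counts)))
  invisible(x)
}

#' Residues of one set in contact with another
#'
#' Residues of `set_p` with any heavy atom strictly within
#' `contact_distance` of any heavy atom of `set_m`.
#'
#' @param frame n x 3 coordinate matrix.
#' @param system the `MolecularSystem`.
#' @param set_p,set_m atom selections.
#' @param contact_distance cutoff (Angstrom, default 4.5).
#' @return sorted integer vector of residue ids from `set_p`.
#' @export
contacting_residues <- function(frame, system, set_p, set_m,
                                contact_distance = 4.5) {
  ip <- heavy_atoms(system, resolve_selection(system, set_p))
  im <- heavy_atoms(system, resolve_selection(system, set_m))
  if (length(ip) == 0L || length(im) == 0L || contact_distance <= 0)
    return(integer(0))
  d <- cross_dist(frame[ip, , drop = FALSE], frame[im, , drop = FALSE])
  touch <- apply(d < contact_distance, 1, any)
  sort(unique(system$atoms$resid[ip[touch]]))
}
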