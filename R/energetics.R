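# Nonbonded 12-6 Lennard-Jones + Coulomb evaluator and the ligand
# interaction-energy partition <Uab> = <U - Ua - Ub>, split into ELECT and
# VDW components. Energies in kJ/mol, distances in Angstrom, charges in e.
#
# LJ: vdw = eps_ab * [ (Rmin_ab/r)^12 - 2 (Rmin_ab/r)^6 ] with
# eps_ab = sqrt(eps_a * eps_b) and Rmin_ab = rmin_a + rmin_b (per-atom
# half-Rmin storage, CHARMM-style combining). Coulomb: ke * qa * qb / r in
# vacuum permittivity, ke = 1389.35 kJ mol^-1 A e^-2.

#' Coulomb constant used throughout (kJ mol^-1 Angstrom e^-2)
#' @export
KE_COULOMB <- 1389.35

energy_breakdown <- function(elect, vdw) {
  structure(list(elect = elect, vdw = vdw, total = elect + vdw),
            class = "EnergyBreakdown")
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat(sprintf("ELECT %.4f  VDW %.4f  Total %.4f kJ/mol\n",
              x$elect, x$vdw, x$total))
  invisible(x)
}

#' Nonbonded pair energy
#'
#' @param atom_a,atom_b single-row atom records (data frames or lists with
#'   `charge`, `rmin`, `epsilon`).
#' @param r center distance (Angstrom, > 0).
#' @return `EnergyBreakdown` with `elect`, `vdw`, `total` (kJ/mol).
#' @export
pair_nonbonded <- function(atom_a, atom_b, r) {
  if (r <= 0) stop("pair distance must be positive")
  for (a in list(atom_a, atom_b))
    if (is.na(a$charge) || is.na(a$rmin) || is.na(a$epsilon))
      stop("atom '", a$name, "' lacks nonbonded parameters")
  eps <- sqrt(atom_a$epsilon * atom_b$epsilon)
  rmin <- atom_a$rmin + atom_b$rmin
  sr6 <- (rmin / r)^6
  vdw <- eps * (sr6^2 - 2 * sr6)
  elect <- KE_COULOMB * atom_a$charge * atom_b$charge / r
  energy_breakdown(elect, vdw)
}

#' Interaction energy between two disjoint atom sets
#'
#' Sums the nonbonded pair energy over all cross pairs (a in A, b in B).
#' For a purely nonbonded model this equals U - Ua - Ub, since intra-set
#' terms cancel in the difference.
#'
#' @param frame n x 3 coordinate matrix.
#' @param system the `MolecularSystem` carrying charges and LJ parameters.
#' @param set_a,set_b disjoint atom selections (strings or indices).
#' @param cutoff pair cutoff in Angstrom, or `NULL` (default) for the full
#'   double sum. Plain truncation, no switching function.
#' @return `EnergyBreakdown` (kJ/mol).
#' @export
interaction_energy <- function(frame, system, set_a, set_b, cutoff = NULL) {
  ia <- resolve_selection(system, set_a)
  ib <- resolve_selection(system, set_b)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty atom set")
  if (length(intersect(ia, ib)) > 0L)
    stop("set_a and set_b overlap (", length(intersect(ia, ib)), " atoms)")
  at <- system$atoms
  need <- c(ia, ib)
  bad <- need[is.na(at$charge[need]) | is.na(at$rmin[need]) |
              is.na(at$epsilon[need])]
  if (length(bad))
    stop("atoms lack nonbonded parameters: ",
         paste(utils::head(at$name[bad], 5), collapse = ", "))
  r <- cross_dist(frame[ia, , drop = FALSE], frame[ib, , drop = FALSE])
  if (any(r == 0)) {
    w <- which(r == 0, arr.ind = TRUE)[1, ]
    stop("zero-distance pair: atoms ", at$serial[ia[w[1]]], " and ",
         at$serial[ib[w[2]]])
  }
  mask <- if (is.null(cutoff)) 1 else (r <= cutoff) * 1
  qq <- outer(at$charge[ia], at$charge[ib])
  elect <- KE_COULOMB * sum(mask * qq / r)
  eps <- outer(at$epsilon[ia], at$epsilon[ib], function(a, b) sqrt(a * b))
  rmin <- outer(at$rmin[ia], at$rmin[ib], `+`)
  sr6 <- (rmin / r)^6
  vdw <- sum(mask * eps * (sr6^2 - 2 * sr6))
  energy_breakdown(elect, vdw)
}

#' Interaction-energy time series
#'
#' Per-frame [interaction_energy()] with mean and sample SD per component.
#'
#' @param traj a `Trajectory`.
#' @param set_a,set_b disjoint atom selections.
#' @param cutoff optional pair cutoff (Angstrom).
#' @param stride frame sampling stride (default 1 = every frame).
#' @return object of class `EnergySeries`: data frame with columns `time`,
#'   `elect`, `vdw`, `total`, and a `summary` attribute (mean/sd rows).
#' @export
energy_series <- function(traj, set_a, set_b, cutoff = NULL, stride = 1L) {
  frames <- seq(1L, n_frames(traj), by = stride)
  out <- matrix(0, length(frames), 3)
  for (k in seq_along(frames)) {
    f <- frames[k]
    e <- tryCatch(
      interaction_energy(frame_coords(traj, f), traj$system, set_a, set_b,
                         cutoff),
      error = function(err)
        stop("frame ", f, ": ", conditionMessage(err), call. = FALSE))
    out[k, ] <- c(e$elect, e$vdw, e$total)
  }
  res <- data.frame(time = traj$times[frames], elect = out[, 1],
                    vdw = out[, 2], total = out[, 3])
  class(res) <- c("EnergySeries", "data.frame")
  attr(res, "summary") <- rbind(elect = mean_sd(out[, 1]),
                                vdw = mean_sd(out[, 2]),
                                total = mean_sd(out[, 3]))
  res
}

#' @export
print.EnergySeries <- function(x, ...) {
  s <- attr(x, "summary")
  cat("Interaction energy over", nrow(x), "frames (kJ/mol):\n")
  for (cmp in rownames(s))
    cat(sprintf("  %-5s %9.2f (+/- %.2f)\n", toupper(cmp), s[cmp, 1], s[cmp, 2]))
  invisible(x)
}
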