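# Membrane penetration geometry from phosphate leaflet sets.
#
# The two phosphate sets MP1/MP2 follow the peripheral-protein convention:
# MP2 is the leaflet on the side the protein inserts into, MP1 the opposite
# leaflet. Per frame,
#   thickness = <Z(MP1)> - <Z(MP2)>
#   depth     = max Z over protein heavy atoms - <Z(MP2)>
#   RPD       = 100 * depth / thickness
# after canonicalizing the frame so <Z(MP1)> > <Z(MP2)> (the whole frame's Z
# is negated when the protein sits above the membrane).

#' Partition phosphates into the two leaflet sets MP1/MP2
#'
#' Phosphates are split by the sign of their Z coordinate relative to the
#' joint phosphate Z-mean. MP2 is the leaflet whose mean Z is nearer the
#' protein's center of geometry; the canonical orientation (mean Z of MP1
#' above MP2) is recorded as a Z sign to apply to the whole frame.
#'
#' @param frame n x 3 coordinate matrix.
#' @param phosphates integer indices of the phosphate atoms.
#' @param protein integer indices of the protein atoms.
#' @return object of class `BilayerModel` with fields `mp1`, `mp2`
#'   (index sets), `zsign` (+1 or -1), `normal_axis`.
#' @export
assign_leaflets <- function(frame, phosphates, protein) {
  if (length(phosphates) < 4L) stop("need at least 4 phosphate atoms")
  if (length(protein) == 0L) stop("empty protein selection")
  z <- frame[phosphates, 3]
  zm <- mean(z)
  upper <- phosphates[z > zm]
  lower <- phosphates[z <= zm]
  if (length(upper) < 2L || length(lower) < 2L)
    stop("degenerate bilayer: fewer than 2 phosphates in a leaflet")
  zprot <- mean(frame[protein, 3])
  mu_up <- mean(frame[upper, 3])
  mu_lo <- mean(frame[lower, 3])
  mp2 <- if (abs(mu_up - zprot) <= abs(mu_lo - zprot)) upper else lower
  mp1 <- if (identical(mp2, upper)) lower else upper
  # canonical orientation: mean Z(MP1) > mean Z(MP2), flip frame Z otherwise
  zsign <- if (mean(frame[mp1, 3]) > mean(frame[mp2, 3])) 1 else -1
  structure(list(mp1 = mp1, mp2 = mp2, zsign = zsign, normal_axis = "Z",
                 n_i = length(mp1), n_j = length(mp2)),
            class = "BilayerModel")
}

#' Per-frame membrane penetration metrics
#'
#' @param frame n x 3 coordinate matrix.
#' @param bilayer a `BilayerModel` valid for this frame.
#' @param protein integer indices of protein atoms; hydrogens are excluded
#'   from the depth maximum via `elements`.
#' @param elements optional character vector of per-atom elements used to
#'   drop hydrogens; when `NULL` all protein atoms are used.
#' @return named numeric vector `c(thickness, depth, rpd)` (Angstrom,
#'   Angstrom, percent).
#' @export
penetration_metrics <- function(frame, bilayer, protein, elements = NULL) {
  if (length(protein) == 0L) stop("empty protein selection")
  if (!is.null(elements)) {
    protein <- protein[elements[protein] != "H"]
    if (length(protein) == 0L) stop("no heavy protein atoms")
  }
  z <- bilayer$zsign * frame[, 3]
  z1 <- mean(z[bilayer$mp1])
  z2 <- mean(z[bilayer$mp2])
  thickness <- z1 - z2
  if (thickness <= 0)
    stop("internal error: non-positive thickness after canonicalization")
  depth <- max(z[protein]) - z2
  c(thickness = thickness, depth = depth, rpd = 100 * depth / thickness)
}

#' Penetration time series over a trajectory
#'
#' Leaflet assignment is recomputed each frame (lipids may in principle
#' flip); metrics and their mean +/- SD are returned.
#'
#' @param traj a `Trajectory`.
#' @param phosphates phosphate selection (string or indices).
#' @param protein protein selection (string or indices).
#' @return object of class `PenetrationProfile`: data frame columns `time`,
#'   `thickness`, `depth`, `rpd` plus a `summary` attribute with mean/sd.
#' @export
penetration_series <- function(traj, phosphates, protein) {
  if (n_frames(traj) < 1L) stop("empty trajectory")
  sys <- traj$system
  ph <- resolve_selection(sys, phosphates)
  pr <- resolve_selection(sys, protein)
  el <- sys$atoms$element
  out <- matrix(0, n_frames(traj), 3)
  for (f in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, f)
    m <- tryCatch({
      bl <- assign_leaflets(fr, ph, pr)
      penetration_metrics(fr, bl, pr, elements = el)
    }, error = function(e)
      stop("frame ", f, ": ", conditionMessage(e), call. = FALSE))
    out[f, ] <- m
  }
  res <- data.frame(time = traj$times, thickness = out[, 1],
                    depth = out[, 2], rpd = out[, 3])
  class(res) <- c("PenetrationProfile", "data.frame")
  attr(res, "summary") <- rbind(thickness = mean_sd(out[, 1]),
                                depth = mean_sd(out[, 2]),
                                rpd = mean_sd(out[, 3]))
  res
}

#' @export
print.PenetrationProfile <- function(x, ...) {
  s <- attr(x, "summary")
  cat("Membrane penetration over", nrow(x), "frames:\n")
  cat(sprintf("  thickness %.2f (+/- %.2f) A\n", s["thickness", 1], s["thickness", 2]))
  cat(sprintf("  depth     %.2f (+/- %.2f) A\n", s["depth", 1], s["depth", 2]))
  cat(sprintf("  RPD       %.2f (+/- %.2f) %%\n", s["rpd", 1], s["rpd", 2]))
  invisible(x)
}
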