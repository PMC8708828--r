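# Carotenoid active-site geometry: distances from the labeled polyene
# carbons (C7, C8, C9, C10, C15, C15') to the catalytic Fe2+, assignment of
# the putative cleavage site to a double bond, and substrate ranking by
# interaction or binding energy. C15' is encoded as atom name "C15P"
# (the prime character is not portable in PDB atom-name columns).

site_labels <- c("C7", "C8", "C9", "C10", "C15", "C15P")

#' Carbon-to-Fe distances of the labeled carotenoid atoms
#'
#' @param x a `Trajectory` or an n x 3 coordinate matrix (single frame).
#' @param system required when `x` is a matrix; taken from the trajectory
#'   otherwise.
#' @param ligand ligand atom selection (string or indices).
#' @param fe selection resolving to the single Fe atom.
#' @return object of class `SiteDistances`: named numeric vector of the six
#'   mean distances (Angstrom); for a trajectory the per-frame matrix is in
#'   the `series` attribute.
#' @export
carbon_fe_distances <- function(x, ligand, fe, system = NULL) {
  if (inherits(x, "Trajectory")) {
    system <- x$system
    frames <- x$coords
  } else {
    if (is.null(system)) stop("system required with a single frame")
    frames <- array(x, dim = c(nrow(x), 3L, 1L))
  }
  il <- resolve_selection(system, ligand)
  ife <- resolve_selection(system, fe)
  if (length(ife) != 1L) stop("fe selection must resolve to exactly one atom")
  nm <- system$atoms$name[il]
  pos <- match(site_labels, nm)
  if (anyNA(pos))
    stop("ligand is missing labeled atom(s): ",
         paste(site_labels[is.na(pos)], collapse = ", "))
  atom_idx <- il[pos]
  nf <- dim(frames)[3]
  series <- matrix(0, nf, length(site_labels),
                   dimnames = list(NULL, site_labels))
  for (f in seq_len(nf)) {
    fr <- matrix(frames[, , f], ncol = 3)
    dv <- fr[atom_idx, , drop = FALSE] -
      matrix(fr[ife, ], length(atom_idx), 3, byrow = TRUE)
    series[f, ] <- sqrt(rowSums(dv^2))
  }
  d <- colMeans(series)
  structure(d, class = "SiteDistances", series = series)
}

#' @export
print.SiteDistances <- function(x, ...) {
  lab <- sub("C15P", "C15'", names(x))
  cat("Carbon-Fe distances (A):",
      paste(sprintf("%s=%.2f", lab, as.numeric(x)), collapse = "  "), "\n")
  invisible(x)
}

#' Assign the cleavage site from carbon-Fe distances
#'
#' Each candidate double bond is scored by the mean of its two carbon
#' distances (C7=C8, C9=C10, C15=C15'); the nearest bond is called. The
#' C15=C15' site corresponds to symmetric cleavage, the other two to
#' asymmetric cleavage. A best-to-second gap at or below `tie_tolerance`
#' yields an ambiguous call.
#'
#' @param d a `SiteDistances` (all six labels present).
#' @param tie_tolerance ambiguity gap (Angstrom, default 0.3).
#' @return object of class `CleavageCall`: list with `site`
#'   (`"C7=C8"`, `"C9=C10"`, `"C15=C15'"` or `"ambiguous"`), `mode`
#'   (`"asymmetric"`, `"symmetric"` or `"ambiguous"`) and `bond_scores`.
#' @export
assign_cleavage_site <- function(d, tie_tolerance = 0.3) {
  need <- setdiff(site_labels, names(d))
  if (length(need)) stop("missing distance(s): ", paste(need, collapse = ", "))
  d <- unclass(d)
  scores <- c("C7=C8" = mean(d[c("C7", "C8")]),
              "C9=C10" = mean(d[c("C9", "C10")]),
              "C15=C15'" = mean(d[c("C15", "C15P")]))
  o <- order(scores)
  gap <- scores[o[2]] - scores[o[1]]
  if (gap <= tie_tolerance) {
    site <- "ambiguous"
    mode <- "ambiguous"
  } else {
    site <- names(scores)[o[1]]
    mode <- if (site == "C15=C15'") "symmetric" else "asymmetric"
  }
  structure(list(site = site, mode = mode, bond_scores = scores),
            class = "CleavageCall")
}

#' @export
print.CleavageCall <- function(x, ...) {
  cat("Cleavage call:", x$site, paste0("(", x$mode, ")"), "- scores:",
      paste(sprintf("%s %.2f", names(x$bond_scores), x$bond_scores),
            collapse = ", "), "\n")
  invisible(x)
}

#' Rank substrates by binding or interaction energy
#'
#' Most negative score first; exact ties are broken lexicographically by
#' ligand label and flagged.
#'
#' @param reports named numeric vector or list mapping ligand label to a
#'   score (kJ/mol).
#' @param mode `"mmpbsa"` or `"uab"` (annotation only).
#' @return data frame with columns `ligand`, `score`, `tied`, best first.
#' @export
rank_substrates <- function(reports, mode = c("mmpbsa", "uab")) {
  mode <- match.arg(mode)
  scores <- unlist(reports)
  if (length(scores) == 0L) stop("empty score map")
  o <- order(scores, names(scores))
  out <- data.frame(ligand = names(scores)[o], score = as.numeric(scores[o]),
                    stringsAsFactors = FALSE)
  out$tied <- duplicated(out$score) | duplicated(out$score, fromLast = TRUE)
  attr(out, "mode") <- mode
  out
}
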