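# Kabsch superposition, RMSD/RMSF profiles and the membrane-vs-solvent
# fluctuation contrast delta-RMSF_i = <RMSF_i>_memb - <RMSF_i>_sol.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile[fit_set, ]` onto `reference[fit_set, ]`.
#'
#' @param mobile,reference n x 3 coordinate matrices (same atom order).
#' @param fit_set atom indices used for the fit (>= 3, non-collinear).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` over the fit set after transform, and `transform(xyz)`, a
#'   function applying the fit to any coordinate matrix.
#' @export
superpose_kabsch <- function(mobile, reference, fit_set = seq_len(nrow(mobile))) {
  if (length(fit_set) < 3L) stop("need at least 3 fit atoms")
  P <- mobile[fit_set, , drop = FALSE]
  Q <- reference[fit_set, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_p <- svd(Pc)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1))
    stop("degenerate (collinear) fit set")
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # row-vector form: x' = x %*% t(R)
  transform <- function(xyz) sweep(sweep(xyz, 2, cp) %*% t(R), 2, cq, `+`)
  fitted <- transform(mobile)[fit_set, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(cq - cp %*% t(R)),
       rmsd = rmsd, transform = transform)
}

#' Per-frame RMSD after superposition
#'
#' @param traj a `Trajectory`.
#' @param reference n x 3 reference coordinates (default frame 1).
#' @param fit_set atom indices for both fitting and RMSD (string selection
#'   or indices; default all atoms).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = NULL, fit_set = NULL) {
  if (is.null(reference)) reference <- frame_coords(traj, 1)
  idx <- if (is.null(fit_set)) seq_len(dim(traj$coords)[1])
         else resolve_selection(traj$system, fit_set)
  vapply(seq_len(n_frames(traj)), function(f)
    superpose_kabsch(frame_coords(traj, f), reference, idx)$rmsd,
    numeric(1))
}

# superpose every frame onto ref over fit idx; returns array like traj$coords
superpose_all <- function(traj, ref, idx) {
  arr <- traj$coords
  for (f in seq_len(dim(arr)[3])) {
    fit <- superpose_kabsch(arr[, , f], ref, idx)
    arr[, , f] <- fit$transform(arr[, , f])
  }
  arr
}

#' Per-residue RMSF profile
#'
#' All frames are superposed onto an iteratively refined mean structure
#' (two passes: fit to frame 1, average, re-fit to the mean, re-average);
#' RMSF_i = sqrt(<|r_i - <r_i>|^2>) per atom, averaged (unweighted) over
#' the atoms of each residue.
#'
#' @param traj a `Trajectory` with >= 2 frames.
#' @param fit_set atoms used for the superposition (selection or indices;
#'   default all atoms).
#' @param report_set atoms whose residues are reported (default `fit_set`).
#' @return object of class `FluctuationProfile`: data frame with columns
#'   `resid` and `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj, fit_set = NULL, report_set = NULL) {
  if (n_frames(traj) < 2L) stop("need at least 2 frames for RMSF")
  n <- dim(traj$coords)[1]
  idx <- if (is.null(fit_set)) seq_len(n)
         else resolve_selection(traj$system, fit_set)
  rep_idx <- if (is.null(report_set)) idx
             else resolve_selection(traj$system, report_set)
  arr <- superpose_all(traj, frame_coords(traj, 1), idx)
  mean_xyz <- apply(arr, c(1, 2), mean)
  tr2 <- trajectory(traj$system, arr, traj$times)
  arr <- superpose_all(tr2, mean_xyz, idx)
  mean_xyz <- apply(arr, c(1, 2), mean)
  dev2 <- (arr - array(mean_xyz, dim = dim(arr)))^2
  msf_atom <- apply(dev2, 1, sum) / dim(arr)[3]   # per-atom <|dr|^2>
  rmsf_atom <- sqrt(msf_atom)
  resid <- traj$system$atoms$resid[rep_idx]
  prof <- stats::aggregate(rmsf_atom[rep_idx],
                           by = list(resid = resid), FUN = mean)
  names(prof)[2] <- "rmsf"
  prof <- prof[order(prof$resid), ]
  rownames(prof) <- NULL
  class(prof) <- c("FluctuationProfile", "data.frame")
  prof
}

#' Membrane-minus-solvent RMSF contrast
#'
#' Per-residue difference of two fluctuation profiles on their residue
#' intersection (membrane-bound minus solvated; negative values mean the
#' membrane rigidifies the residue). Residues present in only one profile
#' are reported in the `missing` attribute, never as zeros.
#'
#' @param memb,sol `FluctuationProfile` objects.
#' @return object of class `DeltaRmsfProfile`: data frame with `resid` and
#'   `delta_rmsf` (Angstrom, signed).
#' @export
delta_rmsf <- function(memb, sol) {
  common <- intersect(memb$resid, sol$resid)
  if (length(common) == 0L) stop("no residues in common between the profiles")
  m <- memb$rmsf[match(common, memb$resid)]
  s <- sol$rmsf[match(common, sol$resid)]
  out <- data.frame(resid = common, delta_rmsf = m - s)
  out <- out[order(out$resid), ]
  rownames(out) <- NULL
  class(out) <- c("DeltaRmsfProfile", "data.frame")
  attr(out, "missing") <- sort(c(setdiff(memb$resid, sol$resid),
                                 setdiff(sol$resid, memb$resid)))
  out
}
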