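#' Construct a trajectory
#'
#' Ordered coordinate frames for a fixed `MolecularSystem`, with one time
#' stamp per frame.
#'
#' @param system a `MolecularSystem`.
#' @param coords numeric array `n_atoms x 3 x n_frames`, or a list of
#'   `n_atoms x 3` matrices.
#' @param times numeric vector of frame times (ps), strictly increasing;
#'   defaults to `0, 1, 2, ...`.
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(system, coords, times = NULL) {
  if (is.list(coords))
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3L, length(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != n_atoms(system))
    stop("frame atom count (", dim(coords)[1],
         ") does not match system atom count (", n_atoms(system), ")")
  nf <- dim(coords)[3]
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  if (length(times) != nf) stop("times length does not match frame count")
  if (nf > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(system = system, coords = coords, times = as.numeric(times)),
            class = "Trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame's coordinates
#' @param traj a `Trajectory`.
#' @param i frame index (1-based).
#' @return n x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range: ", i)
  traj$coords[, , i]
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames x", dim(x$coords)[1], "atoms,",
      sprintf("t = %g..%g ps\n", x$times[1], x$times[length(x$times)]))
  invisible(x)
}
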