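#' Read a molecular structure file
#'
#' PDB and PQR files are parsed through bio3d. For a multi-MODEL PDB the
#' returned system holds MODEL 1. PQR occupancy/B columns populate `charge`
#' and `rmin` (the PQR radius is stored as the per-atom half-Rmin radius).
#'
#' @param path file path.
#' @param format `"pdb"` or `"pqr"`; default guessed from the extension.
#' @param groups optional named list of selection strings evaluated on the
#'   freshly read system to populate groups.
#' @return a `MolecularSystem`.
#' @export
read_structure <- function(path, format = NULL, groups = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  format <- match.arg(format, c("pdb", "pqr"))
  if (format == "pdb") check_pdb_records(path)
  pdb <- if (format == "pdb") {
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  } else {
    bio3d::read.pqr(path)
  }
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no atoms in ", path)
  element <- trimws(if (is.null(at$elesy)) rep("", nrow(at)) else at$elesy)
  blank <- !nzchar(element) | is.na(element)
  if (any(blank)) element[blank] <- infer_element(at$elety[blank])
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), resname = trimws(at$resid),
    resid = at$resno, chain = ifelse(is.na(at$chain), "A", at$chain),
    element = toupper(element),
    x = at$x, y = at$y, z = at$z,
    charge = if (format == "pqr") at$o else NA_real_,
    rmin = if (format == "pqr") at$b else NA_real_,
    epsilon = NA_real_,
    stringsAsFactors = FALSE)
  sys <- molecular_system(atoms)
  if (!is.null(groups))
    sys$groups <- lapply(groups, function(g) resolve_selection(sys, g))
  validate_system(sys)
  sys
}

# cheap well-formedness scan so malformed ATOM records error with the line
check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (length(rec) == 0L) stop("no ATOM/HETATM records in ", path)
  for (i in rec) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed PDB record at line ", i, ": unparseable coordinates")
  }
  invisible(TRUE)
}

pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          occ = 1, b = 0, element = "") {
  # atom name column convention: names up to 3 chars start in column 14
  nm <- ifelse(nchar(name) <= 3L, paste0(" ", formatC(name, width = -3)),
               formatC(name, width = -4))
  sprintf("ATOM  %5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm, "", substr(resname, 1, 3), substr(chain, 1, 1),
          resid %% 10000L, x, y, z, occ, b, element)
}

#' Write a system (and optionally a trajectory) as PDB
#'
#' Writes ATOM records; with a `Trajectory` each frame becomes a
#' MODEL/ENDMDL block. Output is readable by [read_structure()] and
#' [read_trajectory()].
#'
#' @param x a `MolecularSystem` or `Trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "Trajectory")) {
    sys <- x$system
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(n_frames(x))) {
      xyz <- frame_coords(x, f)
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(system_pdb_lines(sys, xyz), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    writeLines(c(system_pdb_lines(x, coords(x)), "END"), path)
  }
  invisible(path)
}

system_pdb_lines <- function(sys, xyz) {
  at <- sys$atoms
  vapply(seq_len(nrow(at)), function(i)
    pdb_atom_line(at$serial[i], at$name[i], at$resname[i], at$chain[i],
                  at$resid[i], xyz[i, 1], xyz[i, 2], xyz[i, 3],
                  element = at$element[i]),
    character(1))
}

#' Write a system as PQR (charge and radius columns)
#'
#' The occupancy column carries the charge (e) and the B column the radius
#' (Angstrom, the per-atom half-Rmin). Readable by
#' `read_structure(format = "pqr")`.
#'
#' @param sys a `MolecularSystem` with charges and radii populated.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(sys, path) {
  at <- sys$atoms
  if (anyNA(at$charge)) stop("system has atoms without charges")
  r <- atom_radii(sys)
  lines <- vapply(seq_len(nrow(at)), function(i) {
    nm <- if (nchar(at$name[i]) <= 3L) paste0(" ", formatC(at$name[i], width = -3))
          else formatC(at$name[i], width = -4)
    sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%8.4f%7.4f",
            at$serial[i], nm, substr(at$resname[i], 1, 3),
            substr(at$chain[i], 1, 1), at$resid[i],
            at$x[i], at$y[i], at$z[i], at$charge[i], r[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a trajectory
#'
#' DCD (CHARMM/NAMD dialect) coordinates are read through bio3d; the header
#' is parsed in-package to recover frame times (`istart`, `nsavc`, `delta`).
#' A multi-MODEL PDB is read through bio3d with uniform 1 ps spacing as the
#' time fallback.
#'
#' @param path file path.
#' @param system the `MolecularSystem` the frames belong to.
#' @param format `"dcd"` or `"multimodel-pdb"`; guessed from the extension.
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path, system, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd"
              else "multimodel-pdb"
  format <- match.arg(format, c("dcd", "multimodel-pdb"))
  n <- n_atoms(system)
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    hdr <- read_dcd_header(path)
    if (hdr$natom != n)
      stop("trajectory atom count (", hdr$natom,
           ") does not match system atom count (", n, ")")
    nf <- nrow(xyz)
    times <- (hdr$istart + (seq_len(nf) - 1L) * hdr$nsavc) * hdr$delta
    if (nf > 1L && !all(diff(times) > 0)) times <- as.numeric(seq_len(nf) - 1L)
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    xyz <- pdb$xyz
    if (ncol(xyz) != 3L * n)
      stop("trajectory atom count (", ncol(xyz) / 3,
           ") does not match system atom count (", n, ")")
    nf <- nrow(xyz)
    times <- as.numeric(seq_len(nf) - 1L)
  }
  arr <- array(0, dim = c(n, 3L, nf))
  for (f in seq_len(nf)) arr[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  trajectory(system, arr, times)
}

read_dcd_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  len <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (len != 84L) {
    endian <- "big"
    seek(con, 0)
    len <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (len != 84L) stop("not a DCD file: ", path)
  }
  magic <- readChar(con, 4, useBytes = TRUE)
  if (magic != "CORD") stop("not a coordinate DCD file: ", path)
  icntrl1 <- readBin(con, "integer", 9, size = 4, endian = endian)
  delta <- readBin(con, "numeric", 1, size = 4, endian = endian)
  icntrl2 <- readBin(con, "integer", 10, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 4, endian = endian)  # trailing 84
  tlen <- readBin(con, "integer", 1, size = 4, endian = endian)
  seek(con, tlen + 4L, origin = "current")
  readBin(con, "integer", 1, size = 4, endian = endian)  # leading 4
  natom <- readBin(con, "integer", 1, size = 4, endian = endian)
  charmm <- icntrl2[10] != 0L
  if (!charmm) {
    # X-PLOR stores delta as a double spanning the float slot; re-read
    seek(con, 4L + 4L + 9L * 4L)
    delta <- readBin(con, "numeric", 1, size = 8, endian = endian)
  }
  list(nframes = icntrl1[1], istart = icntrl1[2], nsavc = max(icntrl1[3], 1L),
       delta = delta, natom = natom, endian = endian)
}

#' Write a trajectory as CHARMM-dialect DCD
#'
#' Little-endian CHARMM-format DCD (version flag 24, no unit cell). Frame
#' times must be uniformly spaced; the spacing is stored in the header
#' `delta` field in ps with `nsavc = 1`.
#'
#' @param traj a `Trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  nf <- n_frames(traj)
  dt <- if (nf > 1L) diff(traj$times) else 1
  delta <- if (nf > 1L) dt[1] else 1
  if (nf > 2L && max(abs(dt - delta)) > 1e-6 * max(abs(dt)))
    warning("DCD stores uniform frame spacing; using the first interval")
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wint(84L)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  istart <- as.integer(round(traj$times[1] / delta))
  wint(c(nf, istart, 1L, nf, 0L, 0L, 0L, 0L, 0L))
  writeBin(delta, con, size = 4, endian = "little")  # float32 (charmm flag)
  wint(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 24L))
  wint(84L)
  title <- formatC("Written by memscan", width = -80)
  wint(4L + 80L)
  wint(1L)
  writeChar(title, con, nchars = 80, eos = NULL)
  wint(4L + 80L)
  wint(4L); wint(dim(traj$coords)[1]); wint(4L)
  n <- dim(traj$coords)[1]
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    for (k in 1:3) {
      wint(4L * n)
      writeBin(as.numeric(xyz[, k]), con, size = 4, endian = "little")
      wint(4L * n)
    }
  }
  invisible(path)
}

#' Read a nonbonded parameter table
#'
#' Whitespace/tab-separated table with header columns `residue`, `atom`,
#' `charge` (e), `rmin` (Angstrom, half-Rmin) and `epsilon` (kJ/mol).
#' Duplicate `(residue, atom)` keys keep the last row, with a warning.
#'
#' @param path file path.
#' @return data frame keyed by `(residue, atom)`.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  needed <- c("residue", "atom", "charge", "rmin", "epsilon")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("parameter table schema error, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  key <- paste(tab$residue, tab$atom)
  if (anyDuplicated(key)) {
    warning("duplicate parameter keys; last occurrence wins: ",
            paste(unique(key[duplicated(key)]), collapse = ", "))
    tab <- tab[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    rownames(tab) <- NULL
  }
  if (any(tab$epsilon < 0)) stop("negative epsilon in parameter table")
  tab[, needed]
}

#' Write a nonbonded parameter table
#' @param params data frame as returned by [read_params()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  utils::write.table(params, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
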