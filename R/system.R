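#' Construct a molecular system
#'
#' A `MolecularSystem` is the static topology every analysis stage consumes:
#' an ordered atom table plus named atom-index groups (e.g. `"protein"`,
#' `"membrane"`, `"ligand"`, `"fe"`).
#'
#' @param atoms data frame with columns `serial` (integer, unique), `name`
#'   (atom name), `resname`, `resid` (integer), `chain`, `element`, `x`,
#'   `y`, `z` (Angstrom) and optionally `charge` (e), `rmin` (Angstrom,
#'   half-Rmin: the per-atom contribution to the pair minimum distance,
#'   combined by `rmin_a + rmin_b`) and `epsilon` (kJ/mol, >= 0).
#' @param groups named list of integer atom-index vectors (1-based row
#'   indices into `atoms`).
#' @return object of class `MolecularSystem`.
#' @export
molecular_system <- function(atoms, groups = list()) {
  required <- c("serial", "name", "resname", "resid", "chain", "element",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atom table is missing column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("charge", "rmin", "epsilon"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  sys <- structure(list(atoms = atoms, groups = groups),
                   class = "MolecularSystem")
  validate_system(sys)
  sys
}

#' Validate a MolecularSystem's invariants
#'
#' Checks finite coordinates, unique serials, non-negative epsilon and
#' in-range group indices. Called by the constructor; exported so generated
#' or edited systems can be re-checked.
#'
#' @param sys a `MolecularSystem`.
#' @return `sys`, invisibly; errors on violation.
#' @export
validate_system <- function(sys) {
  at <- sys$atoms
  if (nrow(at) == 0L) stop("system has zero atoms")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  if (anyDuplicated(at$serial)) stop("duplicate atom serials")
  eps <- at$epsilon
  if (any(!is.na(eps) & eps < 0)) stop("negative lj epsilon")
  n <- nrow(at)
  for (g in names(sys$groups)) {
    idx <- sys$groups[[g]]
    if (length(idx) && (any(idx < 1L) || any(idx > n)))
      stop("group '", g, "' contains out-of-range atom indices")
  }
  invisible(sys)
}

#' Number of atoms in a system
#' @param sys a `MolecularSystem`.
#' @return integer atom count.
#' @export
n_atoms <- function(sys) nrow(sys$atoms)

#' Coordinate matrix of a system
#' @param sys a `MolecularSystem`.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(sys) {
  m <- as.matrix(sys$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace the coordinates of a system
#' @param sys a `MolecularSystem`.
#' @param xyz n x 3 matrix.
#' @return updated system.
#' @export
set_coords <- function(sys, xyz) {
  stopifnot(nrow(xyz) == n_atoms(sys), ncol(xyz) == 3L)
  sys$atoms$x <- xyz[, 1]
  sys$atoms$y <- xyz[, 2]
  sys$atoms$z <- xyz[, 3]
  sys
}

#' @export
print.MolecularSystem <- function(x, ...) {
  cat("MolecularSystem:", n_atoms(x), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), "residues\n")
  if (length(x$groups))
    cat("  groups:", paste(sprintf("%s (%d)", names(x$groups),
                                   lengths(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Merge two systems into one
#'
#' Atom order is first system then second; serials of the second system are
#' shifted past the first's maximum. Groups are kept from both (indices of
#' the second shifted); a name clash takes the union.
#'
#' @param a,b `MolecularSystem` objects.
#' @return merged `MolecularSystem`.
#' @export
merge_systems <- function(a, b) {
  off <- n_atoms(a)
  bt <- b$atoms
  bt$serial <- bt$serial + max(a$atoms$serial)
  atoms <- rbind(a$atoms, bt)
  groups <- a$groups
  for (g in names(b$groups)) {
    shifted <- b$groups[[g]] + off
    groups[[g]] <- if (g %in% names(groups)) sort(union(groups[[g]], shifted))
                   else shifted
  }
  molecular_system(atoms, groups)
}

# element inference from atom names; used when the element column is blank.
# Exact multi-letter matches first (metals, halides), then the leading letter
# of the stripped name for organic elements. Ambiguity errors out rather than
# guessing silently.
infer_element <- function(name) {
  two_letter <- c("FE", "ZN", "MG", "MN", "CU", "CL", "BR")
  vapply(name, function(nm) {
    up <- toupper(trimws(nm))
    stripped <- gsub("[0-9']+", "", up)
    if (stripped %in% two_letter) return(stripped)
    first <- substr(stripped, 1L, 1L)
    if (first %in% c("C", "N", "O", "S", "P", "H")) return(first)
    stop("cannot infer element for atom name '", nm,
         "'; supply the element column")
  }, character(1), USE.NAMES = FALSE)
}

#' Indices of non-hydrogen atoms
#' @param sys a `MolecularSystem`.
#' @param subset optional index vector to restrict to.
#' @return integer indices of heavy atoms.
#' @export
heavy_atoms <- function(sys, subset = NULL) {
  idx <- if (is.null(subset)) seq_len(n_atoms(sys)) else subset
  idx[sys$atoms$element[idx] != "H"]
}

#' Attach nonbonded parameters from a parameter table
#'
#' Looks up every atom by `(resname, name)` in a table read by
#' [read_params()] and fills the `charge`, `rmin` and `epsilon` columns.
#'
#' @param sys a `MolecularSystem`.
#' @param params data frame from [read_params()].
#' @param strict error on atoms missing from the table (default) or leave
#'   them `NA`.
#' @return updated system.
#' @export
apply_params <- function(sys, params, strict = TRUE) {
  key <- paste(sys$atoms$resname, sys$atoms$name)
  pkey <- paste(params$residue, params$atom)
  hit <- match(key, pkey)
  if (strict && anyNA(hit)) {
    miss <- unique(key[is.na(hit)])
    stop("no nonbonded parameters for: ", paste(miss, collapse = ", "))
  }
  ok <- !is.na(hit)
  sys$atoms$charge[ok] <- params$charge[hit[ok]]
  sys$atoms$rmin[ok] <- params$rmin[hit[ok]]
  sys$atoms$epsilon[ok] <- params$epsilon[hit[ok]]
  sys
}

#' Per-atom radii for surface calculations
#'
#' Uses the atom's `rmin` (half-Rmin, a van der Waals radius) when present,
#' otherwise an element-based fallback table.
#'
#' @param sys a `MolecularSystem`.
#' @param subset optional atom indices.
#' @return numeric vector of radii (Angstrom).
#' @export
atom_radii <- function(sys, subset = NULL) {
  idx <- if (is.null(subset)) seq_len(n_atoms(sys)) else subset
  r <- sys$atoms$rmin[idx]
  fallback <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8, H = 1.2,
                FE = 1.3, ZN = 1.39, MG = 1.73, CL = 1.75, BR = 1.85,
                MN = 1.61, CU = 1.4)
  miss <- is.na(r)
  if (any(miss)) {
    el <- sys$atoms$element[idx][miss]
    fb <- fallback[el]
    if (anyNA(fb))
      stop("no radius for element(s): ",
           paste(unique(el[is.na(fb)]), collapse = ", "))
    r[miss] <- fb
  }
  r
}
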