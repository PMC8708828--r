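# Synthetic bilayer / protein / ligand generators.
#
# These are deliberately coarse bead models, not force-field lipids: the
# downstream analyses only need phosphate markers, polar/apolar flags,
# charges and radii, so every generated quantity (leaflet separation,
# per-residue fluctuation amplitudes, carbon-to-Fe offsets) is exact ground
# truth recorded in a manifest for the tests.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# fixture nonbonded parameters by (resname, atom name)
fixture_param_rows <- function() {
  base <- data.frame(
    residue = c("LIP", "LIP", "LIP", "HPB", "PLB", "PLB", "PLB",
                "FE2", "SOL"),
    atom    = c("P",   "C1",  "C2",  "CA",  "CA",  "OD",  "HD",
                "FE",  "OW"),
    charge  = c(-0.8,  0.4,   0.4,   0.0,   -0.1,  -0.4,  0.4,
                2.0,   -0.2),
    rmin    = c(2.1,   2.0,   2.0,   2.0,   2.0,   1.7,   0.2,
                1.3,   1.77),
    epsilon = c(0.6,   0.35,  0.35,  0.3,   0.3,   0.5,   0.1,
                0.02,  0.64),
    stringsAsFactors = FALSE)
  cnames <- c("C3", "C4", "C5", "C6", "C7", "C8", "C9", "C10", "C11",
              "C12", "C13", "C14", "C15", "C15P")
  crt <- data.frame(residue = "CRT", atom = cnames,
                    charge = ifelse(seq_along(cnames) %% 2 == 0, 0.05, -0.05),
                    rmin = 1.99, epsilon = 0.23, stringsAsFactors = FALSE)
  rbind(base, crt)
}

#' Fixture nonbonded parameter table
#'
#' The `(residue, atom)` charge/Rmin/epsilon entries used by all synthetic
#' systems; writable with [write_params()] and re-readable with
#' [read_params()].
#'
#' @return data frame with columns `residue, atom, charge, rmin, epsilon`.
#' @export
fixture_params <- function() fixture_param_rows()

lookup_fixture_params <- function(resname, name) {
  tab <- fixture_param_rows()
  hit <- match(paste(resname, name), paste(tab$residue, tab$atom))
  if (anyNA(hit))
    stop("fixture parameters missing for: ",
         paste(unique(paste(resname, name)[is.na(hit)]), collapse = ", "))
  tab[hit, c("charge", "rmin", "epsilon")]
}

#' Bilayer generator specification
#'
#' @param n_lipids_per_leaflet lipids per leaflet (>= 4).
#' @param phosphate_separation distance between the two mean phosphate
#'   planes (Angstrom); default 39.
#' @param area patch area in Angstrom^2; default 65 A^2 per lipid.
#' @param jitter_sigma Gaussian positional jitter (Angstrom) applied to each
#'   lipid in XY and Z.
#' @param seed RNG seed fixing all randomness.
#' @return object of class `BilayerSpec`.
#' @export
bilayer_spec <- function(n_lipids_per_leaflet = 64, phosphate_separation = 39,
                         area = NULL, jitter_sigma = 0, seed = 1) {
  if (n_lipids_per_leaflet < 4) stop("need at least 4 lipids per leaflet")
  if (phosphate_separation <= 0) stop("phosphate separation must be positive")
  if (jitter_sigma < 0) stop("jitter sigma must be non-negative")
  if (is.null(area)) area <- 65 * n_lipids_per_leaflet
  structure(list(n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 phosphate_separation = phosphate_separation,
                 area = area, jitter_sigma = jitter_sigma,
                 seed = as.integer(seed)),
            class = "BilayerSpec")
}

#' Generate a coarse two-leaflet bilayer
#'
#' Each lipid is one phosphate bead named `"P"` plus two tail beads pointing
#' to the midplane. Leaflet mean phosphate planes sit at +/- separation/2
#' along Z (midplane at Z = 0) before jitter. The membrane group and the
#' ground-truth leaflet labels are attached.
#'
#' @param spec a [bilayer_spec()].
#' @return `MolecularSystem` with groups `membrane`, `phosphates` and a
#'   `manifest` attribute recording leaflet index sets and the true
#'   separation.
#' @export
make_bilayer <- function(spec) {
  n <- spec$n_lipids_per_leaflet
  side <- sqrt(spec$area)
  ngrid <- ceiling(sqrt(n))
  pitch <- side / ngrid
  if (pitch < 4.6)
    stop("packing error: area ", spec$area, " A^2 too small for ", n,
         " lipids per leaflet (pitch ", round(pitch, 2), " A)")
  gx <- (seq_len(ngrid) - (ngrid + 1) / 2) * pitch
  grid <- expand.grid(x = gx, y = gx)[seq_len(n), ]
  half <- spec$phosphate_separation / 2
  with_seed(spec$seed, {
    rows <- list()
    resid <- 0L
    for (leaf in c(1, -1)) {
      jit <- matrix(stats::rnorm(3L * n, 0, spec$jitter_sigma), n, 3)
      for (i in seq_len(n)) {
        resid <- resid + 1L
        px <- grid$x[i] + jit[i, 1]
        py <- grid$y[i] + jit[i, 2]
        pz <- leaf * half + jit[i, 3]
        # tails point toward the midplane
        rows[[length(rows) + 1L]] <- data.frame(
          name = c("P", "C1", "C2"), resname = "LIP", resid = resid,
          chain = "M", element = c("P", "C", "C"),
          x = px, y = py, z = c(pz, pz - leaf * 4, pz - leaf * 8),
          leaflet = if (leaf > 0) "upper" else "lower",
          stringsAsFactors = FALSE)
      }
    }
    at <- do.call(rbind, rows)
  })
  pars <- lookup_fixture_params(at$resname, at$name)
  atoms <- data.frame(serial = seq_len(nrow(at)), at[, 1:8],
                      charge = pars$charge, rmin = pars$rmin,
                      epsilon = pars$epsilon, stringsAsFactors = FALSE)
  leaflet <- at$leaflet
  atoms$leaflet <- NULL
  p_idx <- which(atoms$name == "P")
  sys <- molecular_system(atoms,
                          groups = list(membrane = seq_len(nrow(atoms)),
                                        phosphates = p_idx))
  attr(sys, "manifest") <- list(
    kind = "bilayer",
    phosphate_separation = spec$phosphate_separation,
    n_phosphates = length(p_idx),
    leaflet_upper = which(atoms$name == "P" & leaflet == "upper"),
    leaflet_lower = which(atoms$name == "P" & leaflet == "lower"),
    jitter_sigma = spec$jitter_sigma, seed = spec$seed)
  sys
}

#' Generate a globular protein with two membrane-facing helices and a
#' carotenoid-like ligand at an Fe site
#'
#' The protein is one backbone bead (`CA`) per residue on a spherical shell,
#' except for the requested helix spans which protrude towards -Z as coarse
#' helices of alternating apolar (`HPB`) / polar (`PLB`) residues. Polar
#' residues carry a donor pair (`OD` oxygen + `HD` hydrogen). The ligand is
#' a linear polyene-like carbon chain with labeled atoms C7, C8, C9, C10,
#' C15 and C15P (C15' encoded as `C15P`) at fixed offsets from a single
#' `FE` bead, placed so the C9=C10 bond sits nearest the iron. All atoms
#' carry fixture charges and LJ parameters.
#'
#' @param n_residues protein residue count.
#' @param helix_spans list of 2 integer ranges `c(first, last)` within
#'   `[1, n_residues]`, non-overlapping.
#' @param ligand `"carotenoid"` to include the ligand + Fe, or `NULL`.
#' @param seed RNG seed.
#' @return `MolecularSystem` with groups `protein`, and when the ligand is
#'   present `ligand` and `fe`; ground truth in the `manifest` attribute.
#' @export
make_protein_and_ligand <- function(n_residues = 120,
                                    helix_spans = list(c(30, 46), c(86, 105)),
                                    ligand = "carotenoid", seed = 1) {
  spans <- lapply(helix_spans, as.integer)
  for (sp in spans)
    if (sp[1] < 1 || sp[2] > n_residues || sp[1] > sp[2])
      stop("helix span out of range: ", sp[1], "-", sp[2])
  if (length(spans) == 2) {
    o <- order(vapply(spans, `[`, integer(1), 1))
    spans <- spans[o]
    if (spans[[1]][2] >= spans[[2]][1]) stop("overlapping helix spans")
  }
  helix_res <- unlist(lapply(spans, function(sp) seq(sp[1], sp[2])))
  glob_res <- setdiff(seq_len(n_residues), helix_res)

  rows <- list()
  add_res <- function(resid, resname, base, out_dir = NULL) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = "CA", resname = resname, resid = resid, chain = "P",
      element = "C", x = base[1], y = base[2], z = base[3],
      stringsAsFactors = FALSE)
    if (resname == "PLB") {
      # donor arm points away from the globule so it cannot clash inside
      if (is.null(out_dir)) out_dir <- base / sqrt(sum(base^2))
      od <- base + 1.2 * out_dir
      hd <- od + 0.95 * out_dir
      rows[[length(rows) + 1L]] <<- data.frame(
        name = "OD", resname = "PLB", resid = resid, chain = "P",
        element = "O", x = od[1], y = od[2], z = od[3],
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <<- data.frame(
        name = "HD", resname = "PLB", resid = resid, chain = "P",
        element = "H", x = hd[1], y = hd[2], z = hd[3],
        stringsAsFactors = FALSE)
    }
  }

  # globular shell: deterministic Fibonacci sphere of radius 12 centred at 0
  ngl <- length(glob_res)
  golden <- pi * (3 - sqrt(5))
  for (k in seq_len(ngl)) {
    zz <- (2 * k - 1) / ngl - 1
    rr <- sqrt(max(0, 1 - zz^2))
    ang <- (k - 1) * golden
    base <- 12 * c(rr * cos(ang), rr * sin(ang), zz * 0.85)  # slightly oblate
    resname <- if (glob_res[k] %% 3 == 0) "PLB" else "HPB"
    add_res(glob_res[k], resname, base)
  }
  # helices protrude on -Z below the globule
  for (h in seq_along(spans)) {
    sp <- spans[[h]]
    x0 <- if (h == 1) -6.5 else 6.5
    for (j in seq(sp[1], sp[2])) {
      k <- j - sp[1]
      ang <- k * 100 * pi / 180
      base <- c(x0 + 2.3 * cos(ang), 2.3 * sin(ang), -12 - 1.5 * k)
      resname <- if (k %% 7 < 4) "HPB" else "PLB"
      add_res(j, resname, base,
              out_dir = c(cos(ang), sin(ang), 0))
    }
  }
  at <- do.call(rbind, rows)
  at <- at[order(at$resid), ]
  groups <- list(protein = seq_len(nrow(at)))

  manifest <- list(kind = "protein", n_residues = n_residues,
                   helix_spans = spans, helix_residues = helix_res,
                   seed = seed)
  if (!is.null(ligand)) {
    # linear chain along X inside the globule, Fe above the C9-C10 midpoint
    cnames <- c("C3", "C4", "C5", "C6", "C7", "C8", "C9", "C10", "C11",
                "C12", "C13", "C14", "C15", "C15P")
    spacing <- 1.2
    mid <- (which(cnames == "C9") + which(cnames == "C10")) / 2
    cx <- (seq_along(cnames) - mid) * spacing
    fe_height <- 6.5
    lig <- data.frame(name = cnames, resname = "CRT", resid = n_residues + 1L,
                      chain = "L", element = "C", x = cx, y = 0, z = 0.5,
                      stringsAsFactors = FALSE)
    fe <- data.frame(name = "FE", resname = "FE2", resid = n_residues + 2L,
                     chain = "I", element = "FE",
                     x = 0, y = 0, z = 0.5 + fe_height,
                     stringsAsFactors = FALSE)
    lig_idx <- nrow(at) + seq_len(nrow(lig))
    fe_idx <- nrow(at) + nrow(lig) + 1L
    at <- rbind(at, lig, fe)
    groups$ligand <- lig_idx
    groups$fe <- fe_idx
    labels <- c("C7", "C8", "C9", "C10", "C15", "C15P")
    dlab <- vapply(labels, function(l) {
      i <- which(cnames == l)
      sqrt(cx[i]^2 + fe_height^2)
    }, numeric(1))
    manifest$ligand_fe_distances <- dlab
  }
  pars <- lookup_fixture_params(at$resname, at$name)
  atoms <- data.frame(serial = seq_len(nrow(at)), at,
                      charge = pars$charge, rmin = pars$rmin,
                      epsilon = pars$epsilon, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  sys <- molecular_system(atoms, groups)
  # donor/acceptor assignment lives in the manifest, decoupled from geometry
  od <- which(atoms$name == "OD")
  hd <- which(atoms$name == "HD")
  manifest$donors <- cbind(D = od, H = hd)
  manifest$acceptors <- od
  attr(sys, "manifest") <- manifest
  sys
}

#' Insert a protein(+ligand) system into a bilayer
#'
#' Rigidly translates the protein system so that its lowest heavy-atom Z
#' (the helix tips) sits `penetration` Angstrom below the mean phosphate
#' plane of the upper leaflet, i.e. the protein approaches from +Z and
#' penetrates the upper leaflet by the requested depth, then merges the two
#' systems.
#'
#' @param protein_sys system from [make_protein_and_ligand()].
#' @param bilayer system from [make_bilayer()].
#' @param penetration target penetration depth (Angstrom).
#' @return merged `MolecularSystem`; the manifest records the true depth,
#'   thickness and inserted residues.
#' @export
insert_into_bilayer <- function(protein_sys, bilayer, penetration = 10) {
  bman <- attr(bilayer, "manifest")
  pz <- bilayer$atoms$z[bilayer$groups$phosphates]
  upper_plane <- mean(pz[pz > mean(pz)])
  prot_idx <- protein_sys$groups$protein
  heavy <- heavy_atoms(protein_sys, prot_idx)
  zmin <- min(protein_sys$atoms$z[heavy])
  shift <- (upper_plane - penetration) - zmin
  xyz <- coords(protein_sys)
  xyz[, 3] <- xyz[, 3] + shift
  placed <- set_coords(protein_sys, xyz)
  merged <- merge_systems(bilayer, placed)
  off <- n_atoms(bilayer)
  pman <- attr(protein_sys, "manifest")
  inserted <- sort(unique(placed$atoms$resid[heavy][
    placed$atoms$z[heavy] < upper_plane]))
  man <- list(kind = "membrane-complex",
              thickness = bman$phosphate_separation,
              depth = penetration,
              rpd = 100 * penetration / bman$phosphate_separation,
              leaflet_mp1 = bman$leaflet_lower,
              leaflet_mp2 = bman$leaflet_upper,
              inserted_residues = inserted,
              donors = pman$donors + off,
              acceptors = pman$acceptors + off,
              membrane_acceptors = bilayer$groups$phosphates,
              protein = pman)
  attr(merged, "manifest") <- man
  merged
}

#' Fluctuation specification for trajectory synthesis
#'
#' @param per_residue_sigma per-residue isotropic Gaussian displacement
#'   sigma (Angstrom), one value per residue of the target system.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return object of class `FluctuationSpec`.
#' @export
fluctuation_spec <- function(per_residue_sigma, n_frames, seed = 1) {
  if (any(per_residue_sigma < 0)) stop("negative sigma")
  structure(list(per_residue_sigma = per_residue_sigma,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "FluctuationSpec")
}

#' Synthesize a trajectory with prescribed per-residue fluctuations
#'
#' Frame i = base coordinates + independent isotropic Gaussian displacement
#' per atom (sigma = its residue's value) + optional rigid drift. With
#' sigma s the expected per-atom RMSF is s * sqrt(3).
#'
#' @param system base `MolecularSystem`.
#' @param fluct a [fluctuation_spec()]; sigma length must equal the number
#'   of residues in `system` (unique chain/resid pairs, in order).
#' @param drift optional list with any of `translation` (3-vector, Angstrom
#'   per frame step) and `rotation` (list with `axis` 3-vector and
#'   `degrees_per_frame`, applied about the system centroid).
#' @param dt frame spacing in ps (default 1).
#' @return a `Trajectory` of `n_frames` frames.
#' @export
make_trajectory <- function(system, fluct, drift = NULL, dt = 1) {
  reskey <- paste(system$atoms$chain, system$atoms$resid)
  resus <- unique(reskey)
  sig <- fluct$per_residue_sigma
  if (length(sig) != length(resus))
    stop("per_residue_sigma length (", length(sig),
         ") does not match residue count (", length(resus), ")")
  atom_sig <- sig[match(reskey, resus)]
  base <- coords(system)
  n <- nrow(base)
  nf <- fluct$n_frames
  ctr <- colMeans(base)
  arr <- array(0, dim = c(n, 3L, nf))
  with_seed(fluct$seed, {
    for (f in seq_len(nf)) {
      xyz <- base + matrix(stats::rnorm(3L * n, 0, 1), n, 3) * atom_sig
      if (!is.null(drift)) {
        step <- f - 1L
        if (!is.null(drift$rotation)) {
          ang <- drift$rotation$degrees_per_frame * step * pi / 180
          R <- rotation_about_axis(drift$rotation$axis, ang)
          xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, `+`)
        }
        if (!is.null(drift$translation))
          xyz <- sweep(xyz, 2, drift$translation * step, `+`)
      }
      arr[, , f] <- xyz
    }
  })
  trajectory(system, arr, times = (seq_len(nf) - 1) * dt)
}

#' Write a complete synthetic fixture set to a directory
#'
#' Emits `system.pdb`, `traj.dcd`, `params.tsv` and `manifest.json`
#' (ground-truth record) for a system/trajectory pair.
#'
#' @param dir output directory (created if needed).
#' @param system a `MolecularSystem` (typically with a manifest attribute).
#' @param traj optional `Trajectory`.
#' @return named list of written paths, invisibly.
#' @export
write_fixture_set <- function(dir, system, traj = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(pdb = file.path(dir, "system.pdb"),
                params = file.path(dir, "params.tsv"),
                manifest = file.path(dir, "manifest.json"))
  write_pdb(system, paths$pdb)
  write_params(fixture_params(), paths$params)
  man <- attr(system, "manifest")
  man$n_atoms <- n_atoms(system)
  man$groups <- lapply(system$groups, as.integer)
  jsonlite::write_json(man, paths$manifest, auto_unbox = TRUE, digits = NA)
  if (!is.null(traj)) {
    paths$dcd <- file.path(dir, "traj.dcd")
    write_dcd(traj, paths$dcd)
  }
  invisible(paths)
}
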