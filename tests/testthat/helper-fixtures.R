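# Builders and independent oracles shared across the suite.
# Expected values asserted in the tests were computed with these oracles
# (plain double loops / closed forms), never with the code paths they check.

# minimal hand-built system; xyz is an n x 3 matrix
toy_system <- function(xyz, names = NULL, resname = "TOY", resid = NULL,
                       charge = 0, rmin = 1.7, epsilon = 0.3,
                       element = "C", groups = list()) {
  n <- nrow(xyz)
  molecular_system(data.frame(
    serial = seq_len(n),
    name = if (is.null(names)) paste0("X", seq_len(n)) else names,
    resname = rep_len(resname, n),
    resid = if (is.null(resid)) seq_len(n) else rep_len(resid, n),
    chain = "A", element = rep_len(element, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, n), rmin = rep_len(rmin, n),
    epsilon = rep_len(epsilon, n), stringsAsFactors = FALSE), groups)
}

# random parameterized system for brute-force energy checks; atoms are kept
# at least 2.2 A apart so no LJ term is astronomically steep (the U-Ua-Ub
# oracle would otherwise lose precision to cancellation)
random_system <- function(n, seed, spread = 8, min_sep = 2.2) {
  set.seed(seed)
  xyz <- matrix(stats::runif(3, -spread, spread), 1, 3)
  while (nrow(xyz) < n) {
    cand <- stats::runif(3, -spread, spread)
    d2 <- rowSums(sweep(xyz, 2, cand)^2)
    if (min(d2) >= min_sep^2) xyz <- rbind(xyz, cand)
  }
  toy_system(xyz,
             charge = round(stats::runif(n, -0.8, 0.8), 3),
             rmin = stats::runif(n, 1.2, 2.2),
             epsilon = stats::runif(n, 0.05, 0.6))
}

# independent nonbonded oracle: scalar double loop over unique pairs
brute_pair_energy <- function(at, xyz, idx) {
  elect <- 0; vdw <- 0
  ke <- 1389.35
  if (length(idx) >= 2) {
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1):length(idx)) {
        i <- idx[a]; j <- idx[b]
        r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        elect <- elect + ke * at$charge[i] * at$charge[j] / r
        eps <- sqrt(at$epsilon[i] * at$epsilon[j])
        rmin <- at$rmin[i] + at$rmin[j]
        vdw <- vdw + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
      }
    }
  }
  c(elect = elect, vdw = vdw)
}

# U(all) - U(a) - U(b) oracle for the interaction-energy partition
brute_uab <- function(sys, xyz, ia, ib) {
  at <- sys$atoms
  u <- brute_pair_energy(at, xyz, c(ia, ib))
  ua <- brute_pair_energy(at, xyz, ia)
  ub <- brute_pair_energy(at, xyz, ib)
  u - ua - ub
}

# analytic accessible area of two overlapping spheres (expanded radii
# R1, R2 at center distance d): each sphere loses a cap of height h
two_sphere_sasa <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# membrane-complex fixture shared by several files
make_complex_fixture <- function(sep = 39, pen = 10, jitter = 0, seed = 1,
                                 n_lipids = 36, n_res = 40) {
  bl <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = n_lipids,
                                  phosphate_separation = sep,
                                  jitter_sigma = jitter, seed = seed))
  pr <- make_protein_and_ligand(n_residues = n_res,
                                helix_spans = list(c(10, 18), c(25, 33)),
                                seed = seed)
  insert_into_bilayer(pr, bl, penetration = pen)
}

# uniform-sigma Gaussian fluctuation fixture: n_res residues x 3 atoms
gaussian_rmsf_fixture <- function(n_res = 80, sigma = 0.5, n_frames = 2000,
                                  seed = 11) {
  xyz <- cbind(rep(c(0, 1.5, 0.7), n_res),
               rep(c(0, 0, 1.2), n_res),
               rep(seq_len(n_res) * 3, each = 3))
  sys <- toy_system(xyz, resid = rep(seq_len(n_res), each = 3))
  make_trajectory(sys, fluctuation_spec(rep(sigma, n_res), n_frames,
                                        seed = seed))
}
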