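test_that("noise-free bilayer places leaflet planes exactly at +/- sep/2", {
  bl <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 16,
                                  phosphate_separation = 39,
                                  jitter_sigma = 0))
  man <- attr(bl, "manifest")
  zu <- bl$atoms$z[man$leaflet_upper]
  zl <- bl$atoms$z[man$leaflet_lower]
  expect_equal(mean(zu), 19.5)
  expect_equal(mean(zl), -19.5)
  expect_equal(unique(zu), 19.5)
})

test_that("bilayer phosphate count and jittered leaflet means behave", {
  bl <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 64))
  expect_equal(sum(bl$atoms$name == "P"), 128L)

  blj <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 128,
                                   jitter_sigma = 1.0, seed = 7))
  manj <- attr(blj, "manifest")
  se_bound <- 3 * 1.0 / sqrt(128)
  expect_lt(abs(mean(blj$atoms$z[manj$leaflet_upper]) - 19.5), se_bound)
  expect_lt(abs(mean(blj$atoms$z[manj$leaflet_lower]) + 19.5), se_bound)
})

test_that("generators are pure functions of their seed", {
  a <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 16, jitter_sigma = 0.8,
                                 seed = 42))
  b <- make_bilayer(bilayer_spec(n_lipids_per_leaflet = 16, jitter_sigma = 0.8,
                                 seed = 42))
  expect_identical(a, b)
  p1 <- make_protein_and_ligand(n_residues = 25,
                                helix_spans = list(c(4, 8), c(15, 20)),
                                seed = 3)
  p2 <- make_protein_and_ligand(n_residues = 25,
                                helix_spans = list(c(4, 8), c(15, 20)),
                                seed = 3)
  expect_identical(p1, p2)
  tr1 <- make_trajectory(p1, fluctuation_spec(rep(0.5, 27), 5, seed = 9))
  tr2 <- make_trajectory(p2, fluctuation_spec(rep(0.5, 27), 5, seed = 9))
  expect_identical(tr1$coords, tr2$coords)
})

test_that("generator input validation: packing, spans, sigmas", {
  expect_error(make_bilayer(bilayer_spec(n_lipids_per_leaflet = 100,
                                         area = 100)),
               "packing")
  expect_error(make_protein_and_ligand(n_residues = 20,
                                       helix_spans = list(c(2, 10), c(8, 15))),
               "overlap")
  expect_error(make_protein_and_ligand(n_residues = 20,
                                       helix_spans = list(c(0, 5), c(8, 15))),
               "out of range")
  expect_error(fluctuation_spec(c(0.1, -0.2), 10), "negative")
  pr <- make_protein_and_ligand(n_residues = 10,
                                helix_spans = list(c(2, 4), c(6, 8)))
  expect_error(make_trajectory(pr, fluctuation_spec(rep(0.1, 3), 5)),
               "residue count")
})

test_that("helix-span residues protrude below the globular body", {
  pr <- make_protein_and_ligand(n_residues = 60,
                                helix_spans = list(c(20, 32), c(40, 52)))
  at <- pr$atoms
  hres <- attr(pr, "manifest")$helix_residues
  helix_z <- at$z[at$resid %in% hres & at$name == "CA"]
  glob_z <- at$z[!(at$resid %in% hres) & at$name == "CA" &
                   seq_len(nrow(at)) %in% pr$groups$protein]
  expect_lt(max(helix_z), mean(glob_z))
})

test_that("ligand carbon-to-Fe offsets match the manifest exactly", {
  pr <- make_protein_and_ligand(n_residues = 30,
                                helix_spans = list(c(5, 10), c(20, 25)))
  man <- attr(pr, "manifest")
  d <- carbon_fe_distances(coords(pr), pr$groups$ligand, pr$groups$fe,
                           system = pr)
  expect_equal(as.numeric(d), as.numeric(man$ligand_fe_distances),
               tolerance = 1e-9)
})

test_that("zero-sigma trajectories are static; drift moves frames rigidly", {
  pr <- make_protein_and_ligand(n_residues = 12,
                                helix_spans = list(c(3, 5), c(8, 10)))
  nres <- length(unique(paste(pr$atoms$chain, pr$atoms$resid)))
  tr <- make_trajectory(pr, fluctuation_spec(rep(0, nres), 4))
  for (f in 2:4) expect_equal(tr$coords[, , f], tr$coords[, , 1])

  trd <- make_trajectory(pr, fluctuation_spec(rep(0, nres), 5),
                         drift = list(translation = c(0, 0, -0.1)))
  expect_equal(trd$coords[, 3, 3] - trd$coords[, 3, 1],
               rep(-0.2, n_atoms(pr)))
})

test_that("prescribed sigma is recovered as RMSF = sigma*sqrt(3)", {
  tr <- gaussian_rmsf_fixture(n_res = 30, sigma = 0.4, n_frames = 600,
                              seed = 5)
  prof <- rmsf_profile(tr)
  expect_equal(mean(prof$rmsf), 0.4 * sqrt(3), tolerance = 0.05)
})

test_that("fixture sets round-trip through the writers", {
  cx <- make_complex_fixture(jitter = 0.4, seed = 6)
  nres <- length(unique(paste(cx$atoms$chain, cx$atoms$resid)))
  tr <- make_trajectory(cx, fluctuation_spec(rep(0.2, nres), 3, seed = 2))
  dir <- tempfile("fix")
  paths <- write_fixture_set(dir, cx, tr)
  back <- read_structure(paths$pdb)
  expect_equal(n_atoms(back), n_atoms(cx))
  expect_equal(coords(back), coords(cx), tolerance = 1e-3)
  man <- jsonlite::read_json(paths$manifest, simplifyVector = TRUE)
  expect_equal(man$n_atoms, n_atoms(cx))
  expect_equal(man$depth, 10)
  traj_back <- read_trajectory(paths$dcd, back)
  expect_equal(n_frames(traj_back), 3L)
  expect_lt(max(abs(traj_back$coords - tr$coords)), 1e-3)
})
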