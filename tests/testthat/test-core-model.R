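test_that("PDB write/read round-trips names, residues and coordinates", {
  xyz <- matrix(c(1.234, -2.5, 0.001,
                  10.1, 20.2, -30.3,
                  0, 0, 0,
                  5.5, 6.25, 7.125,
                  -1, -2, -3), 5, 3, byrow = TRUE)
  sys <- toy_system(xyz, names = c("CA", "OD", "C15P", "P", "FE"),
                    resname = "TOY", element = c("C", "O", "C", "P", "FE"))
  path <- tempfile(fileext = ".pdb")
  write_pdb(sys, path)
  back <- read_structure(path)
  expect_equal(n_atoms(back), 5L)
  expect_equal(back$atoms$name, sys$atoms$name)
  expect_equal(back$atoms$resid, sys$atoms$resid)
  expect_equal(coords(back), coords(sys), tolerance = 1e-3)
})

test_that("PQR charge and radius columns populate the atom record", {
  lines <- c(
    "ATOM      1  O1  TOY A   1       0.000   0.000   0.000 -0.8000 1.7000",
    "ATOM      2  N1  TOY A   2       1.500   0.000   0.000  0.3000 1.5500",
    "END")
  path <- tempfile(fileext = ".pqr")
  writeLines(lines, path)
  sys <- read_structure(path, format = "pqr")
  expect_equal(sys$atoms$charge, c(-0.8, 0.3))
  expect_equal(sys$atoms$rmin, c(1.7, 1.55))
})

test_that("malformed PDB records error with the offending line", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1       1.000   2.000   3.000",
               "ATOM      2  CB  ALA A   1       1.000   bad     3.000"),
             path)
  expect_error(read_structure(path), "line 2")
  writeLines("REMARK nothing here", path)
  expect_error(read_structure(path), "no ATOM")
})

test_that("generated fixture round-trips with the advertised atom count", {
  pr <- make_protein_and_ligand(n_residues = 30,
                                helix_spans = list(c(5, 10), c(20, 25)))
  path <- tempfile(fileext = ".pdb")
  write_pdb(pr, path)
  back <- read_structure(path)
  expect_equal(n_atoms(back), n_atoms(pr))
  expect_equal(coords(back), coords(pr), tolerance = 1e-3)
})

test_that("multi-MODEL PDB yields one frame per MODEL and MODEL 1 as structure", {
  pr <- make_protein_and_ligand(n_residues = 12,
                                helix_spans = list(c(3, 5), c(8, 10)))
  tr <- make_trajectory(pr, fluctuation_spec(rep(0.3, 14), 3, seed = 2))
  path <- tempfile(fileext = ".pdb")
  write_pdb(tr, path)
  back <- read_trajectory(path, pr)
  expect_equal(n_frames(back), 3L)
  expect_equal(back$coords[, , 2], tr$coords[, , 2], tolerance = 1e-3)
  sys1 <- read_structure(path)
  expect_equal(coords(sys1), tr$coords[, , 1], tolerance = 1e-3)
})

test_that("DCD written by the generator reads back frame-exactly", {
  pr <- make_protein_and_ligand(n_residues = 15,
                                helix_spans = list(c(3, 6), c(9, 12)))
  tr <- make_trajectory(pr, fluctuation_spec(rep(0.4, 17), 50, seed = 7),
                        dt = 2)
  path <- tempfile(fileext = ".dcd")
  write_dcd(tr, path)
  back <- read_trajectory(path, pr)
  expect_equal(n_frames(back), 50L)
  expect_lt(max(abs(back$coords - tr$coords)), 1e-3)
  expect_equal(back$times, tr$times, tolerance = 1e-5)
})

test_that("trajectory atom-count mismatch reports both counts", {
  pr <- make_protein_and_ligand(n_residues = 15,
                                helix_spans = list(c(3, 6), c(9, 12)))
  tr <- make_trajectory(pr, fluctuation_spec(rep(0.1, 17), 2, seed = 1))
  path <- tempfile(fileext = ".dcd")
  write_dcd(tr, path)
  small <- toy_system(matrix(0, 3, 3))
  expect_error(read_trajectory(path, small),
               paste0(n_atoms(pr), ".*3|3.*", n_atoms(pr)))
})

test_that("single-frame structure promotes to a one-frame trajectory", {
  sys <- toy_system(matrix(rnorm(9), 3, 3))
  tr <- trajectory(sys, array(coords(sys), dim = c(3, 3, 1)))
  expect_equal(n_frames(tr), 1L)
  expect_equal(frame_coords(tr, 1), coords(sys))
})

test_that("parameter table: schema, duplicates-last-wins, fixture count", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("residue\tatom\tcharge\trmin\tepsilon",
               "LIP\tP\t-0.8\t2.1\t0.6"), path)
  tab <- read_params(path)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$charge, -0.8)

  writeLines(c("residue\tatom\tcharge\trmin\tepsilon",
               "LIP\tP\t-0.8\t2.1\t0.6",
               "LIP\tP\t-0.5\t2.0\t0.5"), path)
  expect_warning(tab2 <- read_params(path), "duplicate")
  expect_equal(tab2$charge, -0.5)

  writeLines(c("residue\tatom\tcharge", "LIP\tP\t-0.8"), path)
  expect_error(read_params(path), "missing column")

  write_params(fixture_params(), path)
  tab3 <- read_params(path)
  expect_equal(nrow(tab3), nrow(fixture_params()))
  expect_equal(tab3$epsilon, fixture_params()$epsilon)
})

test_that("selection language resolves names, groups, ranges and booleans", {
  cx <- make_complex_fixture()
  man <- attr(cx, "manifest")
  p <- select_atoms(cx, "name P")
  expect_equal(p, sort(c(man$leaflet_mp1, man$leaflet_mp2)))
  c9 <- select_atoms(cx, "group ligand and name C9")
  expect_length(c9, 1L)
  expect_equal(cx$atoms$name[c9], "C9")
  pr <- make_protein_and_ligand(n_residues = 10, ligand = NULL,
                                helix_spans = list(c(2, 4), c(6, 8)))
  expect_length(select_atoms(pr, "not group protein"), 0L)
  rng <- select_atoms(cx, "group protein and resid 10:18")
  expect_true(all(cx$atoms$resid[rng] %in% 10:18))
  expect_setequal(select_atoms(cx, "name P or name C1"),
                  union(select_atoms(cx, "name P"),
                        select_atoms(cx, "name C1")))
})

test_that("selections are idempotent and set-algebra consistent", {
  cx <- make_complex_fixture()
  exprs <- c("name P", "group protein", "resname PLB",
             "group protein and resname HPB",
             "(group ligand or group fe) and not name C9")
  for (e in exprs) {
    a <- select_atoms(cx, e)
    expect_identical(a, select_atoms(cx, e))
  }
  a <- select_atoms(cx, "group protein")
  b <- select_atoms(cx, "resname PLB")
  expect_true(all(select_atoms(cx, "group protein and resname PLB") %in% a))
  expect_true(all(a %in% select_atoms(cx, "group protein or resname PLB")))
})

test_that("selection syntax errors carry a position", {
  sys <- toy_system(matrix(0, 2, 3), names = c("A1", "A2"))
  expect_error(select_atoms(sys, "name"), "expected a value")
  expect_error(select_atoms(sys, "frobnicate A1"), "token 1")
  expect_error(select_atoms(sys, "(name A1"), "expected '\\)'")
  expect_error(select_atoms(sys, "group nope"), "unknown group")
})

test_that("system invariants are enforced", {
  at <- data.frame(serial = c(1, 1), name = c("A", "B"), resname = "X",
                   resid = 1, chain = "A", element = "C",
                   x = 0, y = 0, z = 0)
  expect_error(molecular_system(at), "duplicate")
  at$serial <- 1:2
  at$x <- c(0, NaN)
  expect_error(molecular_system(at), "finite")
  at$x <- c(0, 1)
  at$epsilon <- c(0.2, -0.1)
  expect_error(molecular_system(at), "epsilon")
  expect_error(infer_element("Q9"), "cannot infer")
})
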