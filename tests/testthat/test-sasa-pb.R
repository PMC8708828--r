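test_that("SASA of an isolated sphere matches 4 pi (r + probe)^2", {
  s <- sasa(matrix(0, 1, 3), radii = 1.6, probe = 1.4, n_points = 960)
  expect_equal(s$total, 4 * pi * 3^2, tolerance = 0.005)
  expect_equal(s$total, sum(s$per_atom))
})

test_that("distant atoms are additive; overlapping pair matches cap formula", {
  far <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), radii = c(1.6, 2.0),
              probe = 1.4, n_points = 960)
  expect_equal(far$total, 4 * pi * (3^2 + 3.4^2), tolerance = 1e-9)

  for (d in c(2.0, 3.5, 5.0)) {
    near <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), radii = c(1.6, 2.0),
                 probe = 1.4, n_points = 960)
    expect_equal(near$total, two_sphere_sasa(3, 3.4, d), tolerance = 0.01)
  }
})

test_that("adding an atom never increases the SASA of the existing ones", {
  set.seed(31)
  for (k in 1:4) {
    n <- 6
    xyz <- matrix(runif(3 * n, -4, 4), n, 3)
    radii <- runif(n, 1.2, 2.0)
    before <- sasa(xyz[-n, , drop = FALSE], radii[-n], n_points = 480)
    after <- sasa(xyz, radii, n_points = 480)
    expect_true(all(after$per_atom[-n] <= before$per_atom + 1e-9))
  }
})

test_that("SASA input validation", {
  expect_error(sasa(matrix(0, 1, 3), -1), "positive")
  expect_error(sasa(matrix(0, 1, 3), 1.5, n_points = 50), "92")
  expect_error(sasa(matrix(0, 2, 3), 1.5), "length")
})

test_that("PB solver: zero charge and no dielectric contrast give zero", {
  expect_identical(pb_solve(matrix(0, 1, 3), 0, 2, pb_grid(spacing = 0.8)), 0)
  e <- pb_solve(matrix(0, 1, 3), 1, 2,
                pb_grid(spacing = 0.8, eps_in = 4, eps_out = 4))
  expect_equal(e, 0, tolerance = 1e-6)
})

test_that("PB solver reproduces the Born ion at coarse spacing", {
  born <- -(KE_COULOMB / 4) * (1 - 1 / 78.54)
  e <- pb_solve(matrix(c(0.13, 0.07, 0.11), 1, 3), 1, 2,
                pb_grid(spacing = 0.8, eps_in = 1, eps_out = 78.54))
  expect_equal(e, born, tolerance = 0.05)
})

test_that("PB boundary margin and convergence guards fire", {
  expect_error(pb_grid(spacing = 0.8, margin = 2), "at least 6")
  expect_error(pb_solve(matrix(0, 1, 3), 1, 2,
                        pb_grid(spacing = 0.8, max_iter = 2L)),
               "converge")
})

test_that("solvation terms: nonpolar is gamma * SASA + beta", {
  sys <- toy_system(matrix(c(0, 0, 0), 1, 3), charge = 1, rmin = 2)
  fr <- coords(sys)
  cfg0 <- mmpbsa_config(grid = pb_grid(spacing = 0.8), gamma = 0, beta = 0)
  t0 <- solvation_terms(fr, sys, 1L, cfg0)
  expect_equal(unname(t0["g_nonpolar"]), 0)
  cfg <- mmpbsa_config(grid = pb_grid(spacing = 0.8), gamma = 0.0227)
  t1 <- solvation_terms(fr, sys, 1L, cfg)
  a <- sasa(fr, atom_radii(sys), 1.4, 240)$total
  expect_equal(unname(t1["g_nonpolar"]), 0.0227 * a, tolerance = 1e-9)
  expect_equal(unname(t1["g_polar"]),
               pb_solve(fr, 1, 2, cfg$grid), tolerance = 1e-9)
})

test_that("MM/PBSA with solvation disabled collapses to the Uab energy", {
  sys <- random_system(8, seed = 17, spread = 5)
  arr <- array(coords(sys), dim = c(8, 3, 1))
  tr <- trajectory(sys, arr)
  cfg <- mmpbsa_config(grid = pb_grid(spacing = 0.8, eps_in = 2, eps_out = 2),
                       gamma = 0, beta = 0)
  br <- mmpbsa_binding(tr, 1:5, 6:8, cfg)
  uab <- interaction_energy(coords(sys), sys, 1:5, 6:8)
  expect_equal(br$g_binding, uab$total, tolerance = 1e-9)
  expect_equal(br$g_polar, 0)
  expect_equal(br$t_ds, 0)
})

test_that("MM/PBSA report equals an independently scripted four-term sum", {
  at <- data.frame(serial = 1:5, name = c("O1", "O2", "O3", "C1", "C2"),
                   resname = "TOY", resid = c(1, 1, 1, 2, 2), chain = "A",
                   element = c("O", "O", "O", "C", "C"),
                   x = c(0, 2.5, 1.2, 6.0, 7.5),
                   y = c(0, 0.4, 2.1, 0.3, 1.1),
                   z = c(0, 0.2, -0.8, 0.5, -0.2),
                   charge = c(-0.4, 0.3, 0.1, -0.2, 0.2),
                   rmin = c(1.7, 1.7, 1.7, 2.0, 2.0),
                   epsilon = c(0.5, 0.5, 0.5, 0.3, 0.3))
  sys <- molecular_system(at)
  fr <- coords(sys)
  arr <- array(fr, dim = c(5, 3, 2))
  arr[, , 2] <- arr[, , 2] + 1.1      # rigid shift: terms must repeat
  tr <- trajectory(sys, arr)
  grid <- pb_grid(spacing = 0.8)
  cfg <- mmpbsa_config(grid = grid, gamma = 0.0227, beta = 0.4)
  br <- mmpbsa_binding(tr, 1:3, 4:5, cfg)

  # independent script: each term assembled from the low-level operations
  mm <- sum(brute_uab(sys, fr, 1:3, 4:5))
  radii <- at$rmin
  pol <- pb_solve(fr, at$charge, radii, grid) -
    pb_solve(fr[1:3, ], at$charge[1:3], radii[1:3], grid) -
    pb_solve(fr[4:5, ], at$charge[4:5], radii[4:5], grid)
  np <- (0.0227 * sasa(fr, radii, 1.4, 240)$total + 0.4) -
    (0.0227 * sasa(fr[1:3, ], radii[1:3], 1.4, 240)$total + 0.4) -
    (0.0227 * sasa(fr[4:5, ], radii[4:5], 1.4, 240)$total + 0.4)
  expect_equal(br$mm_gas[1], mm, tolerance = 1e-9)
  expect_equal(br$g_polar[1], pol, tolerance = 1e-9)
  expect_equal(br$g_nonpolar[1], np, tolerance = 1e-9)
  expect_equal(br$g_binding[1], mm + pol + np, tolerance = 1e-9)

  # term closure per frame and rigid-motion stability
  expect_equal(br$g_binding,
               br$mm_gas + br$g_polar + br$g_nonpolar - br$t_ds,
               tolerance = 1e-9)
  expect_equal(br$mm_gas[2], br$mm_gas[1], tolerance = 1e-9)
  expect_equal(br$g_nonpolar[2], br$g_nonpolar[1], tolerance = 1e-9)
  expect_equal(br$g_polar[2], br$g_polar[1], tolerance = 0.5)
  s <- attr(mmpbsa_binding(trajectory(sys, array(fr, dim = c(5, 3, 2))),
                           1:3, 4:5, cfg), "summary")
  expect_equal(unname(s[, "sd"]), rep(0, 5))
})

test_that("MM/PBSA contract errors", {
  sys <- random_system(6, seed = 3)
  tr <- trajectory(sys, array(coords(sys), dim = c(6, 3, 1)))
  expect_error(mmpbsa_binding(tr, 1:4, 3:6), "overlap")
  expect_error(mmpbsa_binding(tr, integer(0), 1:3), "empty")
})
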