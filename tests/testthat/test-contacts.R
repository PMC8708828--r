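test_that("contact surface area: zero when separated, symmetric, non-negative", {
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(100, 0, 0), c(103, 0, 0))
  sys <- toy_system(xyz, rmin = 1.8)
  fr <- coords(sys)
  expect_equal(contact_surface_area(fr, sys, 1:2, 3:4), 0, tolerance = 1e-9)
  near <- toy_system(rbind(c(0, 0, 0), c(0, 0, 4.0)), rmin = 1.8)
  a_pm <- contact_surface_area(coords(near), near, 1L, 2L)
  a_mp <- contact_surface_area(coords(near), near, 2L, 1L)
  expect_gt(a_pm, 0)
  expect_equal(a_pm, a_mp, tolerance = 1e-9)
  half <- contact_surface_area(coords(near), near, 1L, 2L, single_sided = TRUE)
  expect_equal(half, a_pm / 2, tolerance = 1e-12)
  expect_error(contact_surface_area(fr, sys, 1:3, 3:4), "overlap")
})

test_that("sphere resting on a bead plane matches the direct SASA difference", {
  plane <- as.matrix(expand.grid(x = c(-3, 0, 3), y = c(-3, 0, 3)))
  xyz <- rbind(cbind(plane, 0), c(0, 0, 4.2))
  sys <- toy_system(xyz, rmin = 1.8)
  fr <- coords(sys)
  got <- contact_surface_area(fr, sys, 10L, 1:9, n_points = 960)
  # oracle: buried-area formula assembled directly from three SASA calls
  r <- atom_radii(sys)
  s_p <- sasa(fr[10, , drop = FALSE], r[10], 1.4, 960)$total
  s_m <- sasa(fr[1:9, ], r[1:9], 1.4, 960)$total
  s_all <- sasa(fr, r, 1.4, 960)$total
  expect_equal(got, s_p + s_m - s_all, tolerance = 0.02 * got)
  expect_gt(got, 0)
})

test_that("hydrogen bonds respect both geometric criteria", {
  # donor O at origin with H pointing +x; acceptors along +x at 2.9 and 6.0
  xyz <- rbind(c(0, 0, 0), c(0.95, 0, 0), c(2.9, 0, 0), c(6.0, 0, 0),
               c(2.0, 2.9, 0))
  sys <- toy_system(xyz, names = c("OD", "HD", "A1", "A2", "A3"),
                    element = c("O", "H", "O", "O", "O"))
  tr <- trajectory(sys, array(coords(sys), dim = c(5, 3, 1)))
  hb <- hydrogen_bonds(tr, donors = cbind(1L, 2L), acceptors = c(3L, 4L, 5L))
  # A1: d = 2.9, angle 180 -> counted. A2: d = 6.0 -> rejected.
  # A3: d = 3.52 -> rejected by distance.
  expect_equal(hb$counts, 1L)
  expect_equal(hb$per_frame[[1]]$acceptor, 3L)
  expect_equal(hb$per_frame[[1]]$angle, 180, tolerance = 1e-6)

  # bent geometry: same distance, angle ~90 degrees -> rejected
  xyz2 <- rbind(c(0, 0, 0), c(0.95, 0, 0), c(0.95, 2.8, 0))
  sys2 <- toy_system(xyz2, names = c("OD", "HD", "A1"),
                     element = c("O", "H", "O"))
  tr2 <- trajectory(sys2, array(coords(sys2), dim = c(3, 3, 1)))
  hb2 <- hydrogen_bonds(tr2, cbind(1L, 2L), 3L)
  expect_equal(hb2$counts, 0L)
  loose <- hydrogen_bonds(tr2, cbind(1L, 2L), 3L,
                          hbond_criteria(3.5, angle_min = 80))
  expect_equal(loose$counts, 1L)
})

test_that("bond counts are monotone in the criteria and average correctly", {
  set.seed(41)
  n_d <- 4
  base_d <- cbind(runif(n_d, -3, 3), runif(n_d, -3, 3), 0)
  xyz <- rbind(base_d,
               base_d + matrix(rep(c(0.95, 0, 0), each = n_d), n_d),
               base_d + matrix(rep(c(2.8, 0, 0), each = n_d), n_d))
  sys <- toy_system(xyz, element = rep(c("O", "H", "O"), each = n_d))
  arr <- array(0, dim = c(nrow(xyz), 3, 3))
  for (f in 1:3) arr[, , f] <- xyz
  tr <- trajectory(sys, arr)
  donors <- cbind(1:n_d, n_d + 1:n_d)
  acceptors <- 2 * n_d + 1:n_d
  hb <- hydrogen_bonds(tr, donors, acceptors)
  expect_equal(hb$mean_count, n_d)         # k bonds every frame -> mean k
  tight_d <- hydrogen_bonds(tr, donors, acceptors, hbond_criteria(1.0, 150))
  loose_d <- hydrogen_bonds(tr, donors, acceptors, hbond_criteria(8, 150))
  expect_true(all(tight_d$counts <= hb$counts))
  expect_true(all(hb$counts <= loose_d$counts))
  strict_a <- hydrogen_bonds(tr, donors, acceptors, hbond_criteria(3.5, 179))
  expect_true(all(strict_a$counts <= hb$counts))
  expect_error(hydrogen_bonds(tr, donors[0, , drop = FALSE], acceptors),
               "empty")
})

test_that("contacting residues: separation, cutoffs and monotonicity", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 4.0), c(0, 0, 30))
  sys <- toy_system(xyz, resid = c(1, 2, 3))
  fr <- coords(sys)
  expect_equal(contacting_residues(fr, sys, 2:3, 1L, 4.5), 2L)
  expect_equal(contacting_residues(fr, sys, 2:3, 1L, 3.0), integer(0))
  expect_equal(contacting_residues(fr, sys, 2:3, 1L, 0), integer(0))
  expect_equal(contacting_residues(fr, sys, 2:3, 1L, 50), c(2L, 3L))

  cx <- make_complex_fixture()
  fr <- coords(cx)
  touching <- contacting_residues(fr, cx, cx$groups$protein,
                                  cx$groups$membrane, 4.5)
  # oracle: direct scripted minimum heavy-atom distance per protein residue
  ip <- cx$groups$protein[cx$atoms$element[cx$groups$protein] != "H"]
  im <- cx$groups$membrane[cx$atoms$element[cx$groups$membrane] != "H"]
  expected <- sort(unique(unlist(lapply(split(ip, cx$atoms$resid[ip]),
    function(idx) {
      dmin <- min(apply(fr[idx, , drop = FALSE], 1, function(p)
        min(sqrt(colSums((t(fr[im, ]) - p)^2)))))
      if (dmin < 4.5) cx$atoms$resid[idx[1]] else NULL
    }))))
  expect_equal(touching, as.integer(expected))
  expect_gt(length(touching), 0)
  # monotone in the cutoff
  t6 <- contacting_residues(fr, cx, cx$groups$protein,
                            cx$groups$membrane, 6.0)
  expect_true(all(touching %in% t6))
})

test_that("contact area series on the membrane fixture is stable and in scale", {
  cx <- make_complex_fixture(n_lipids = 36)
  nres <- length(unique(paste(cx$atoms$chain, cx$atoms$resid)))
  tr <- make_trajectory(cx, fluctuation_spec(rep(0, nres), 2))
  ca <- contact_area_series(tr, "group protein", "group membrane",
                            n_points = 240)
  expect_equal(attr(ca, "summary")["area", "sd"], 0)
  expect_gt(ca$area[1], 0)
})
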