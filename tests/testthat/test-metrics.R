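test_that("isodose volumes follow the closed-threshold convention", {
  inst <- random_instance(1)
  expect_true(all(isodose_volume(inst$dose, 0)$voxels))
  expect_false(any(isodose_volume(inst$dose, max(inst$dose$values) + 1)$voxels))
  # exactly-at-level voxels are included
  g <- grid_spec(3, spacing = 1)
  d <- dose_grid(array(15, dim = c(3, 3, 3)), g)
  expect_true(all(isodose_volume(d, 15)$voxels))
  # monotone non-increasing volume in level
  vols <- vapply(seq(0, 25, by = 2.5),
                 function(l) sum(isodose_volume(inst$dose, l)$voxels),
                 numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("the 15 Gy isodose volume of the calibrated sphere matches the kernel inverse", {
  ph <- single_sphere_phantom()
  r15 <- 9 + (19.2 - 15) / 3.3  # kernel crosses 15 Gy at 10.27 mm
  v <- volume_cc(isodose_volume(ph$dose, 15))
  shell <- 4 * pi * r15^2 * 1.25 / 1000
  expect_lt(abs(v - sphere_cc(r15)), shell / 2)
})

test_that("DCK/ICK partition matches the exhaustive voxel oracle exactly", {
  for (seed in 1:20) {
    inst <- random_instance(seed, max_dose = 25)
    part <- dck_ick_partition(inst$dose, inst$mask)
    # brute-force enumeration over voxels
    idx <- which(inst$mask$voxels)
    n_dck <- 0L; n_ick <- 0L
    for (i in idx) {
      v <- inst$dose$values[i]
      if (v >= 20) n_dck <- n_dck + 1L
      else if (v >= 15) n_ick <- n_ick + 1L
    }
    expect_identical(part$dck_fraction, 100 * n_dck / length(idx))
    expect_identical(part$ick_fraction, 100 * n_ick / length(idx))
    # conservation: dck + ick is exactly the V15 coverage fraction
    expect_identical(part$dck_fraction + part$ick_fraction, part$v15_fraction)
  }
})

test_that("partition handles fully covered and sandwiched targets", {
  g <- grid_spec(5, spacing = 1)
  m <- voxelize_sphere(g, c(0, 0, 0), 1.5)
  covered <- dck_ick_partition(dose_grid(array(25, dim = g$shape), g), m)
  expect_equal(covered$dck_fraction, 100)
  expect_equal(covered$ick_fraction, 0)
  between <- dck_ick_partition(dose_grid(array(17, dim = g$shape), g), m)
  expect_equal(between$dck_fraction, 0)
  expect_equal(between$ick_fraction, 100)
  empty <- structure_mask(array(FALSE, dim = g$shape), g)
  expect_error(dck_ick_partition(dose_grid(array(17, dim = g$shape), g),
                                 empty), "empty")
})

test_that("iterative covering-dose search equals the voxel-min oracle", {
  for (seed in 1:200) {
    inst <- random_instance(seed, n = 6, max_dose = 24)
    got <- min_covering_dose(inst$dose, inst$mask, step = 0.1)
    oracle <- floor(min(inst$dose$values[inst$mask$voxels]) / 0.1) * 0.1
    expect_equal(got, oracle)
  }
  # uniform dose is its own covering dose
  g <- grid_spec(4, spacing = 1)
  m <- structure_mask(array(TRUE, dim = g$shape), g)
  expect_equal(min_covering_dose(dose_grid(array(20, dim = g$shape), g), m),
               20)
})

test_that("covering dose is monotone in translation magnitude", {
  ph <- single_sphere_phantom()
  mcds <- vapply(c(0, 0.5, 1, 2), function(s) {
    pert <- apply_setup_error(ph$dose, transform6dof(dx = s),
                              within = ph$brain_mask)
    min_covering_dose(pert, ph$ptv_masks[[1]])
  }, numeric(1))
  expect_true(all(diff(mcds) < 0))
})

test_that("relaxed covered-fraction tolerates single-voxel artifacts", {
  g <- grid_spec(5, spacing = 1)
  vals <- array(20, dim = g$shape)
  vals[1, 1, 1] <- 5  # one cold voxel
  d <- dose_grid(vals, g)
  m <- structure_mask(array(TRUE, dim = g$shape), g)
  expect_equal(min_covering_dose(d, m), 5)
  expect_equal(min_covering_dose(d, m, covered_fraction = 0.99), 20)
})

test_that("DVH is a monotone cumulative curve agreeing with Vx", {
  inst <- random_instance(3)
  tab <- dvh(inst$dose, inst$mask, bin_width = 0.5)
  expect_equal(tab$volume_cc[1], volume_cc(inst$mask))
  expect_equal(tab$volume_pct[1], 100)
  expect_true(all(diff(tab$volume_cc) <= 0))
  expect_lt(tab$volume_cc[nrow(tab)], tab$volume_cc[1])
  # cross-oracle: DVH at a bin edge equals v_x there, equals brute force
  for (lev in c(0, 5.5, 12, 20)) {
    bf <- sum(inst$dose$values[inst$mask$voxels] >= lev) *
      voxel_volume_cc(inst$dose$grid)
    expect_equal(v_x(inst$dose, inst$mask, lev), bf)
    i <- which(abs(tab$dose_gy - lev) < 1e-9)
    if (length(i)) expect_equal(tab$volume_cc[i], bf)
  }
  # uniform dose drops in a single step at its value
  g <- grid_spec(4, spacing = 1)
  m <- structure_mask(array(TRUE, dim = g$shape), g)
  u <- dvh(dose_grid(array(10, dim = g$shape), g), m, bin_width = 0.5)
  expect_true(all(u$volume_pct[u$dose_gy <= 10] == 100))
  expect_true(all(u$volume_pct[u$dose_gy > 10] == 0))
  expect_error(dvh(dose_grid(array(1, dim = g$shape), g),
                   structure_mask(array(FALSE, dim = g$shape), g)), "empty")
})

test_that("v_x limits and OAR max dose behave", {
  inst <- random_instance(4)
  expect_equal(v_x(inst$dose, inst$mask, 0), volume_cc(inst$mask))
  expect_equal(v_x(inst$dose, inst$mask, max(inst$dose$values) + 1), 0)
  expect_equal(oar_max_dose(inst$dose, inst$mask),
               max(inst$dose$values[inst$mask$voxels]))
  # uniform field and dose-scaling linearity
  g <- grid_spec(4, spacing = 1)
  m <- structure_mask(array(TRUE, dim = g$shape), g)
  expect_equal(oar_max_dose(dose_grid(array(7, dim = g$shape), g), m), 7)
  scaled <- dose_grid(inst$dose$values * 2.5, inst$dose$grid)
  expect_equal(oar_max_dose(scaled, inst$mask),
               2.5 * oar_max_dose(inst$dose, inst$mask))
  empty <- structure_mask(array(FALSE, dim = inst$dose$grid$shape),
                          inst$dose$grid)
  expect_error(oar_max_dose(inst$dose, empty), "empty")
})

test_that("set algebra refuses mismatched lattices", {
  inst <- random_instance(5)
  other <- grid_spec(8, spacing = 2)
  m2 <- structure_mask(array(TRUE, dim = c(8, 8, 8)), other)
  expect_error(v_x(inst$dose, m2, 10), "lattice")
  expect_error(dck_ick_partition(inst$dose, m2), "lattice")
})
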