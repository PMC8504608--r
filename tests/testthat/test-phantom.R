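test_that("cohort geometry sampling respects placement constraints", {
  specs <- sample_cohort_geometry(16, seed = 42)
  expect_length(specs, 16)
  centers <- t(vapply(specs, `[[`, numeric(3), "center"))
  ptv_r <- vapply(specs, function(s) s$gtv_radius + s$ptv_margin, numeric(1))
  # distances to isocenter inside the configured range
  d <- sqrt(rowSums(centers^2))
  expect_true(all(d >= 22 & d <= 89))
  # pairwise PTV disjointness with the two-voxel buffer
  for (i in 1:15) for (j in (i + 1):16) {
    sep <- sqrt(sum((centers[i, ] - centers[j, ])^2))
    expect_gt(sep, ptv_r[i] + ptv_r[j] + 2 * 1.25)
  }
  # GTV volumes inside the cohort range
  v <- sphere_cc(vapply(specs, `[[`, numeric(1), "gtv_radius"))
  expect_true(all(v >= 0.02 & v <= 11.5))
})

test_that("cohort sampling is bit-reproducible and degenerate placement works", {
  a <- sample_cohort_geometry(5, seed = 7)
  b <- sample_cohort_geometry(5, seed = 7)
  expect_identical(a, b)
  c1 <- sample_cohort_geometry(5, seed = 8)
  expect_false(identical(a, c1))
  # single target with zero distance range sits at the isocenter
  s <- sample_cohort_geometry(1, seed = 1,
                              cohort_ranges = list(gtv_cc = c(1, 1),
                                                   distance_cm = c(0, 0)))
  expect_equal(s[[1]]$center, c(0, 0, 0))
})

test_that("impossible placement fails with an explicit constraint error", {
  expect_error(
    sample_cohort_geometry(16, seed = 1,
                           cohort_ranges = list(gtv_cc = c(11, 11.5),
                                                distance_cm = c(2.2, 2.3)),
                           max_attempts = 200),
    "separation constraint")
})

test_that("voxelized sphere volume tracks the analytic volume", {
  # relative error bounded by h/r, shrinking with spacing
  for (r in c(2, 5, 10)) {
    g <- grid_spec(ceiling(2 * (r + 2) / 0.5) + 1, spacing = 0.5)
    v <- volume_cc(voxelize_sphere(g, c(0, 0, 0), r))
    expect_lt(abs(v - sphere_cc(r)) / sphere_cc(r), 0.5 / r)
  }
  g_coarse <- grid_spec(13, spacing = 1.25)
  g_fine <- grid_spec(31, spacing = 0.5)
  err <- function(g, h) abs(volume_cc(voxelize_sphere(g, c(0, 0, 0), 5)) -
                              sphere_cc(5)) / sphere_cc(5)
  expect_lt(err(g_fine), err(g_coarse))

  # a 2.2 cc lesion on the 1.25 mm study grid, within half a voxel shell
  r22 <- radius_from_cc(2.2)
  m <- voxelize_sphere(grid_spec(25, spacing = 1.25), c(0, 0, 0), r22)
  shell <- 4 * pi * r22^2 * 1.25 / 1000
  expect_lt(abs(volume_cc(m) - 2.2), shell / 2)

  # sub-voxel sphere on a voxel centre occupies exactly that voxel
  g <- grid_spec(11, spacing = 1.25)
  m1 <- voxelize_sphere(g, c(0, 0, 0), 0.1)
  expect_identical(sum(m1$voxels), 1L)
  expect_warning(voxelize_sphere(g, c(100, 100, 100), 2), "outside")
})

test_that("dose kernel hits its plateau, boundary and fall-off values", {
  ph <- single_sphere_phantom()  # GTV 8 mm, PTV 9 mm, centred on the grid
  ctr <- (ph$grid$shape + 1) / 2
  val <- function(i_off) ph$dose$values[ctr[1] + i_off, ctr[2], ctr[3]]
  expect_equal(val(0), 20 / 0.75)                     # plateau = Rx / IDL
  expect_equal(val(8), 19.2 - 3.3 * (10 - 9))         # x = 10 mm
  expect_equal(val(9), 19.2 - 3.3 * (11.25 - 9))      # x = 11.25 mm
  # minimum dose over PTV voxels is the boundary dose up to the sampling
  # shortfall of the outermost voxel centre
  expect_equal(min(ph$dose$values[ph$ptv_masks[[1]]$voxels]), 19.2,
               tolerance = 1 / 19.2)
  expect_true(all(ph$dose$values >= 0))
  expect_true(max(ph$dose$values) <= 20 / 0.75 + 1e-9)
  expect_error(synthesize_dose(ph$grid, list()), "non-empty")
})

test_that("fall-off evaluates to 15 Gy at the calibrated distance", {
  ph <- single_sphere_phantom()
  # 19.2 - 3.3 * 1.273 = 15.0; the kernel is linear along the +x ray beyond
  # the PTV surface so trilinear sampling there is exact
  s <- icksim:::.interp_trilinear(ph$dose$values, ph$grid,
                                  9 + 1.273, 0, 0)
  expect_equal(s$values, 19.2 - 3.3 * 1.273, tolerance = 1e-3)
})

test_that("multi-target dose is additive and bounded", {
  t1 <- target_spec(c(-15, 0, 0), 4)
  t2 <- target_spec(c(15, 0, 0), 4)
  g <- grid_spec(41, spacing = 1.25)
  d_sum <- synthesize_dose(g, list(t1, t2))
  d_max <- synthesize_dose(g, list(t1, t2), combine = "max")
  expect_true(all(d_sum$values >= d_max$values - 1e-12))
  expect_true(max(d_sum$values) <= 2 * 20 / 0.75 + 1e-9)
  d1 <- synthesize_dose(g, list(t1))
  d2 <- synthesize_dose(g, list(t2))
  expect_equal(d_sum$values, d1$values + d2$values)
})

test_that("phantom masks are nested and serialization round-trips", {
  specs <- sample_cohort_geometry(3, seed = 11,
                                  cohort_ranges = list(gtv_cc = c(0.1, 1),
                                                       distance_cm = c(1.5, 2.5)))
  ph <- build_phantom(specs, brain_radius = 35, seed = 11,
                      oars = list(brainstem = list(center = c(0, 0, -20),
                                                   semiaxes = c(8, 8, 12))))
  for (i in seq_along(specs)) {
    expect_false(any(ph$gtv_masks[[i]]$voxels & !ph$ptv_masks[[i]]$voxels))
    expect_false(any(ph$ptv_masks[[i]]$voxels & !ph$brain_mask$voxels))
  }
  expect_named(ph$oar_masks, "brainstem")
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  ph2 <- read_phantom(dir)
  expect_equal(ph2$dose$values, ph$dose$values)
  expect_identical(ph2$brain_mask$voxels, ph$brain_mask$voxels)
  expect_identical(ph2$ptv_masks[[2]]$voxels, ph$ptv_masks[[2]]$voxels)
  expect_equal(ph2$targets[[1]]$center, ph$targets[[1]]$center)
})

test_that("invalid grid and target parameters are rejected", {
  expect_error(grid_spec(11, spacing = 0), "spacing")
  expect_error(grid_spec(11, origin = c(0, 0, 0),
                         isocenter = c(100, 0, 0)), "isocenter")
  expect_error(target_spec(c(0, 0, 0), -1), "gtv_radius")
  expect_error(target_spec(c(0, 0, 0), 5, idl_fraction = 1.2), "idl_fraction")
  expect_error(target_spec(c(0, 0, 0), 5, boundary_min_dose = 25),
               "boundary_min_dose")
  expect_error(dose_grid(array(-1, dim = c(2, 2, 2)), grid_spec(2)),
               "non-negative")
})
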