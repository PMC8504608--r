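test_that("transform matrices behave as a rigid group", {
  expect_equal(build_matrix(transform6dof()), diag(4))
  t <- transform6dof(dx = 1, dy = -0.5, dz = 2, pitch = 2, roll = -1.5,
                     yaw = 1, pivot = c(3, -2, 7))
  M <- build_matrix(t)
  R <- M[1:3, 1:3]
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
  expect_lt(max(abs(M %*% invert_transform(t) - diag(4))), 1e-9)
  # pivot invariance under pure rotation
  tr <- transform6dof(pitch = 2, roll = 2, yaw = 2, pivot = c(3, -2, 7))
  expect_equal(drop(transform_points(tr, matrix(c(3, -2, 7), 1))),
               c(3, -2, 7), tolerance = 1e-12)
})

test_that("pure rotation displacement follows the chord formula", {
  # chord = 2 R sin(theta/2), exact to 1e-6 mm, and linear in R
  for (theta in c(0.5, 1, 2)) {
    t <- transform6dof(yaw = theta)
    for (R in c(25, 50, 80)) {
      p <- matrix(c(R, 0, 0), 1)
      disp <- sqrt(sum((transform_points(t, p) - p)^2))
      expect_equal(disp, 2 * R * sin(theta * pi / 360), tolerance = 1e-6)
    }
  }
  # rotations preserve distance to the pivot
  t <- transform6dof(pitch = 2, roll = 1, yaw = 2, pivot = c(1, 2, 3))
  set.seed(1)
  pts <- matrix(stats::rnorm(30, sd = 40), ncol = 3)
  d0 <- sqrt(rowSums(sweep(pts, 2, c(1, 2, 3))^2))
  d1 <- sqrt(rowSums(sweep(transform_points(t, pts), 2, c(1, 2, 3))^2))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("opposite-sign errors give mirror-symmetric displacements", {
  p <- matrix(c(40, -20, 30), 1)
  # translations mirror exactly
  tp <- transform6dof(dx = 2, dy = 2, dz = 2)
  tm <- transform6dof(dx = -2, dy = -2, dz = -2)
  expect_equal(transform_points(tp, p) - p, -(transform_points(tm, p) - p))
  # single-axis rotations give equal displacement magnitudes
  for (ax in c("pitch", "roll", "yaw")) {
    args_p <- stats::setNames(list(2), ax)
    args_m <- stats::setNames(list(-2), ax)
    dp <- transform_points(do.call(transform6dof, args_p), p) - p
    dm <- transform_points(do.call(transform6dof, args_m), p) - p
    expect_equal(sqrt(sum(dp^2)), sqrt(sum(dm^2)), tolerance = 1e-12)
  }
})

test_that("error_vector builds the coupled six-DOF setting", {
  t <- error_vector(2, 2)
  expect_equal(unlist(t[c("dx", "dy", "dz", "pitch", "roll", "yaw")]),
               c(dx = 2, dy = 2, dz = 2, pitch = 2, roll = 2, yaw = 2))
  expect_equal(build_matrix(error_vector(0, 0)), diag(4))
  r1 <- error_vector(1, 1, signs = "random", seed = 3)
  r2 <- error_vector(1, 1, signs = "random", seed = 3)
  expect_identical(r1, r2)
  expect_true(all(abs(unlist(r1[c("dx", "dy", "dz")])) == 1))
  s <- error_vector(1, 1, signs = c(-1, 1, -1, 1, 1, -1))
  expect_equal(c(s$dx, s$dy, s$dz, s$pitch, s$roll, s$yaw),
               c(-1, 1, -1, 1, 1, -1))
  expect_error(transform6dof(pitch = 15), "10 degrees")
})

test_that("identity resampling is exact and translations shift linear fields", {
  ph <- single_sphere_phantom()
  out <- apply_setup_error(ph$dose, transform6dof())
  expect_identical(out$values, ph$dose$values)
  expect_equal(attr(out, "clipped_fraction"), 0)

  # linear field d = x + 30: a +2 mm error samples the field 2 mm upstream
  g <- grid_spec(21, spacing = 1)
  X <- array(rep(axis_coords(g, 1), times = 21 * 21), dim = g$shape)
  d <- dose_grid(X + 30, g)
  shifted <- suppressWarnings(apply_setup_error(d, transform6dof(dx = 2)))
  interior <- 3:19
  expect_equal(shifted$values[interior, , ],
               d$values[interior, , ] - 2, tolerance = 1e-12)
})

test_that("a 2 mm translation lowers the covering dose by the kernel fall-off", {
  ph <- single_sphere_phantom()
  mcd0 <- min_covering_dose(ph$dose, ph$ptv_masks[[1]])
  pert <- apply_setup_error(ph$dose, transform6dof(dx = 2),
                            within = ph$brain_mask)
  mcd2 <- min_covering_dose(pert, ph$ptv_masks[[1]])
  expect_equal(mcd0 - mcd2, 3.3 * 2, tolerance = 0.15)
})

test_that("round-trip resampling error stays within the kink bound", {
  ph <- single_sphere_phantom()
  t <- error_vector(1, 1, pivot = ph$grid$isocenter)
  d1 <- apply_setup_error(ph$dose, t, within = ph$brain_mask)
  d2 <- apply_setup_error(d1, invert_transform(t), within = ph$brain_mask)
  interior <- voxelize_sphere(ph$grid, c(0, 0, 0), 15)$voxels
  dd <- abs(d2$values - ph$dose$values)[interior]
  # worst case for two trilinear passes of a piecewise-linear radial kernel:
  # (max slope change at a kink) * h / 2; the GTV->PTV ramp dominates
  slope_ramp <- (20 / 0.75 - 19.2) / 1
  expect_lt(max(dd), slope_ramp * 1.25 / 2)
  expect_lt(mean(dd), 0.5)
})

test_that("out-of-grid resampling is zero-filled and reported", {
  ph <- single_sphere_phantom()
  expect_warning(
    pert <- apply_setup_error(ph$dose, transform6dof(dx = 15)),
    "outside the dose grid")
  expect_gt(attr(pert, "clipped_fraction"), 0.01)
  expect_true(all(pert$values >= 0))
  # clipping restricted to the brain mask is smaller than the global one
  pert2 <- suppressWarnings(
    apply_setup_error(ph$dose, transform6dof(dx = 15),
                      within = ph$brain_mask))
  expect_lte(attr(pert2, "clipped_fraction"), attr(pert, "clipped_fraction"))
})
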