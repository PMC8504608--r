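# shared fixtures, built in code at test time

# single calibrated sphere: GTV 8 mm, PTV 9 mm, defaults 19.2 Gy / 3.3 Gy/mm
single_sphere_phantom <- function(gtv_radius = 8, brain_radius = 20, ...) {
  build_phantom(list(target_spec(c(0, 0, 0), gtv_radius, ...)),
                brain_radius = brain_radius)
}

# small random dose + mask pair for exhaustive-oracle comparisons
random_instance <- function(seed, n = 8, max_dose = 25) {
  set.seed(seed)
  g <- grid_spec(n, spacing = 1)
  d <- dose_grid(array(stats::runif(n^3, 0, max_dose), dim = rep(n, 3)), g)
  m <- array(stats::runif(n^3) < 0.4, dim = rep(n, 3))
  if (!any(m)) m[1] <- TRUE
  list(dose = d, mask = structure_mask(m, g, "random"))
}

expect_same_files <- function(a, b) {
  expect_identical(readBin(a, "raw", file.size(a)),
                   readBin(b, "raw", file.size(b)))
}
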