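#' Target (lesion) specification
#'
#' Geometry and dose-kernel parameters of one spherical brain metastasis.
#' The analytic kernel is piecewise linear in the radial distance r from
#' the target centre:
#'
#' * `r <= gtv_radius`: plateau at `prescription / idl_fraction` (the plan
#'   maximum implied by prescribing to a 70-80% isodose line);
#' * `gtv_radius < r <= gtv_radius + ptv_margin`: linear descent from the
#'   plateau to `boundary_min_dose` at the PTV surface;
#' * beyond the PTV surface: linear descent at `falloff_gradient` Gy/mm,
#'   clipped at 0 Gy.
#'
#' The defaults (`boundary_min_dose = 19.2` Gy, `falloff_gradient = 3.3`
#' Gy/mm) calibrate the kernel so that an unperturbed plan just covers the
#' PTV at 19.2 Gy and the covering dose declines by 3.3 Gy per mm of
#' target displacement, emulating the steep peripheral gradients of
#' clinical single-isocenter multitarget VMAT radiosurgery plans.
#'
#' @param center mm coordinates of the lesion centre.
#' @param gtv_radius GTV radius in mm (> 0).
#' @param ptv_margin uniform GTV-to-PTV expansion in mm (default 1.0).
#' @param prescription prescription dose in Gy (default 20).
#' @param idl_fraction prescription isodose line as a fraction of the plan
#'   maximum, in (0, 1] (default 0.75, the middle of the 70-80% range).
#' @param boundary_min_dose dose in Gy at the PTV surface (default 19.2).
#' @param falloff_gradient dose fall-off beyond the PTV surface in Gy/mm
#'   (default 3.3).
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(center, gtv_radius, ptv_margin = 1.0,
                        prescription = 20, idl_fraction = 0.75,
                        boundary_min_dose = 19.2, falloff_gradient = 3.3) {
  stopifnot(length(center) == 3L, all(is.finite(center)))
  if (gtv_radius <= 0) stop("gtv_radius must be > 0")
  if (ptv_margin < 0) stop("ptv_margin must be >= 0")
  if (idl_fraction <= 0 || idl_fraction > 1) {
    stop("idl_fraction must lie in (0, 1]")
  }
  if (boundary_min_dose <= 0 || boundary_min_dose > prescription) {
    stop("boundary_min_dose must lie in (0, prescription]")
  }
  if (falloff_gradient <= 0) stop("falloff_gradient must be > 0")
  structure(
    list(center = as.numeric(center), gtv_radius = gtv_radius,
         ptv_margin = ptv_margin, prescription = prescription,
         idl_fraction = idl_fraction, boundary_min_dose = boundary_min_dose,
         falloff_gradient = falloff_gradient),
    class = "target_spec"
  )
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf(
    "<target_spec> centre (%s) mm, GTV r=%.2f mm (%.3f cc), PTV margin %.1f mm\n",
    paste(format(x$center, digits = 3), collapse = ", "),
    x$gtv_radius, sphere_cc(x$gtv_radius), x$ptv_margin))
  invisible(x)
}

#' Sphere volume in cc from a radius in mm
#' @param radius_mm radius in mm.
#' @return Volume in cc.
#' @export
sphere_cc <- function(radius_mm) 4 / 3 * pi * radius_mm^3 / 1000

#' Sphere radius in mm from a volume in cc
#' @param volume_cc volume in cc.
#' @return Radius in mm.
#' @export
radius_from_cc <- function(volume_cc) (3 * volume_cc * 1000 / (4 * pi))^(1 / 3)

# run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never clobbers user seeds
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Sample multi-lesion cohort geometry
#'
#' Draws lesion specifications with the statistical structure of a
#' multi-metastasis radiosurgery cohort: GTV volumes log-uniform over a
#' configurable range (default 0.02-11.5 cc), target centres uniformly
#' distributed in direction at a distance-to-isocenter drawn uniformly
#' from a configurable range (default 2.2-8.9 cm), with pairwise
#' non-overlapping PTVs enforced by rejection sampling.
#'
#' @param n_lesions number of lesions, 1 to 16.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param cohort_ranges list with elements `gtv_cc` (min/max GTV volume in
#'   cc) and `distance_cm` (min/max distance to isocenter in cm).
#' @param isocenter mm coordinates of the isocenter.
#' @param spacing_mm grid spacing used for the separation guard (two
#'   voxels are added to the required PTV-PTV centre separation).
#' @param max_attempts rejection-sampling cap per cohort (default 10000).
#' @param ... further arguments passed to [target_spec()] (margins, kernel
#'   calibration).
#' @return List of `n_lesions` [target_spec()] objects.
#' @export
#' @examples
#' specs <- sample_cohort_geometry(5, seed = 7)
#' length(specs)
sample_cohort_geometry <- function(n_lesions, seed,
                                   cohort_ranges = list(
                                     gtv_cc = c(0.02, 11.5),
                                     distance_cm = c(2.2, 8.9)),
                                   isocenter = c(0, 0, 0),
                                   spacing_mm = 1.25,
                                   max_attempts = 10000, ...) {
  if (n_lesions < 1 || n_lesions > 16) {
    stop("n_lesions must be between 1 and 16")
  }
  gtv_rng <- sort(cohort_ranges$gtv_cc)
  dist_rng <- sort(cohort_ranges$distance_cm) * 10  # cm -> mm
  stopifnot(gtv_rng[1] > 0, dist_rng[1] >= 0)
  with_seed(seed, {
    specs <- vector("list", n_lesions)
    ptv_r <- numeric(n_lesions)
    centers <- matrix(NA_real_, n_lesions, 3)
    attempts <- 0L
    i <- 1L
    while (i <= n_lesions) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf(paste0(
          "placement failed for lesion %d after %d attempts: could not ",
          "satisfy the pairwise PTV separation constraint ",
          "(centre separation > sum of PTV radii + 2 voxels)"),
          i, max_attempts))
      }
      v <- 10^stats::runif(1, log10(gtv_rng[1]), log10(gtv_rng[2]))
      r_gtv <- radius_from_cc(v)
      d <- stats::runif(1, dist_rng[1], dist_rng[2])
      u <- stats::rnorm(3)
      nu <- sqrt(sum(u^2))
      dir <- if (nu > 0) u / nu else c(1, 0, 0)
      ctr <- isocenter + d * dir
      spec <- target_spec(center = ctr, gtv_radius = r_gtv, ...)
      rp <- spec$gtv_radius + spec$ptv_margin
      ok <- TRUE
      if (i > 1L) {
        sep <- sqrt(colSums((t(centers[seq_len(i - 1L), , drop = FALSE]) -
                               ctr)^2))
        ok <- all(sep > ptv_r[seq_len(i - 1L)] + rp + 2 * spacing_mm)
      }
      if (ok) {
        specs[[i]] <- spec
        ptv_r[i] <- rp
        centers[i, ] <- ctr
        i <- i + 1L
      }
    }
    specs
  })
}

#' Voxelize a sphere onto a grid
#'
#' Membership is voxel-centre-in-sphere (no partial volume), matching
#' treatment-planning contour rasterization at the study resolution and
#' keeping the downstream Boolean algebra exactly testable.
#'
#' @param grid a [grid_spec()].
#' @param center sphere centre in mm.
#' @param radius sphere radius in mm (> 0).
#' @param name mask name.
#' @return A [structure_mask()]; warns if the sphere lies entirely outside
#'   the grid (empty mask).
#' @export
voxelize_sphere <- function(grid, center, radius, name = "sphere") {
  stopifnot(inherits(grid, "grid_spec"))
  if (radius <= 0) stop("radius must be > 0")
  vox <- .dist2_field(grid, center) <= radius^2
  if (!any(vox)) {
    warning("sphere lies entirely outside the grid: returning an empty mask")
  }
  structure_mask(vox, grid, name = name)
}

#' Voxelize an axis-aligned ellipsoid onto a grid
#'
#' Used for optional organ-at-risk surrogates (hippocampi, brainstem,
#' optic apparatus).
#'
#' @param grid a [grid_spec()].
#' @param center ellipsoid centre in mm.
#' @param semiaxes semi-axis lengths in mm (length 3, > 0).
#' @param name mask name.
#' @return A [structure_mask()].
#' @export
voxelize_ellipsoid <- function(grid, center, semiaxes, name = "oar") {
  stopifnot(inherits(grid, "grid_spec"), length(semiaxes) == 3L)
  if (any(semiaxes <= 0)) stop("semiaxes must be > 0")
  u2 <- ((axis_coords(grid, 1) - center[1]) / semiaxes[1])^2
  v2 <- ((axis_coords(grid, 2) - center[2]) / semiaxes[2])^2
  w2 <- ((axis_coords(grid, 3) - center[3]) / semiaxes[3])^2
  structure_mask(outer(outer(u2, v2, "+"), w2, "+") <= 1, grid, name = name)
}

# radial dose kernel of one target, vectorised over r (mm)
.target_kernel <- function(r, t) {
  dmax <- t$prescription / t$idl_fraction
  rg <- t$gtv_radius
  rp <- t$gtv_radius + t$ptv_margin
  d <- numeric(length(r))
  inside <- r <= rg
  d[inside] <- dmax
  if (t$ptv_margin > 0) {
    ramp <- r > rg & r <= rp
    d[ramp] <- dmax + (r[ramp] - rg) / (rp - rg) * (t$boundary_min_dose - dmax)
  }
  tail <- r > rp
  d[tail] <- pmax(0, t$boundary_min_dose - t$falloff_gradient * (r[tail] - rp))
  d
}

#' Synthesize an analytic SRS-like dose distribution
#'
#' Sums (or voxelwise-maximises) the per-target radial kernels described
#' in [target_spec()].  Dose is additive physically, so `combine = "sum"`
#' is the default; at cohort-range target separations the cross-target
#' tail contribution is negligible, and `combine = "max"` is provided for
#' sensitivity checks.
#'
#' @param grid a [grid_spec()].
#' @param targets non-empty list of [target_spec()] objects.
#' @param combine `"sum"` (default) or `"max"`.
#' @return A [dose_grid()].
#' @export
synthesize_dose <- function(grid, targets, combine = c("sum", "max")) {
  combine <- match.arg(combine)
  stopifnot(inherits(grid, "grid_spec"))
  if (length(targets) == 0) stop("targets must be non-empty")
  acc <- array(0, dim = grid$shape)
  for (t in targets) {
    r <- sqrt(.dist2_field(grid, t$center))
    k <- array(.target_kernel(as.vector(r), t), dim = grid$shape)
    acc <- if (combine == "sum") acc + k else pmax(acc, k)
  }
  dose_grid(acc, grid)
}

#' Assemble a multi-lesion patient phantom
#'
#' Builds the voxel lattice, per-target GTV/PTV masks, a spherical
#' whole-brain mask (grown if needed so that every PTV is contained),
#' optional ellipsoidal OAR masks, and the synthetic dose distribution.
#'
#' @param targets list of [target_spec()] objects (e.g. from
#'   [sample_cohort_geometry()]).
#' @param spacing grid spacing in mm (default 1.25).
#' @param brain_radius whole-brain sphere radius in mm (default 80; grown
#'   automatically to contain all PTVs).
#' @param isocenter mm coordinates of the isocenter (default origin).
#' @param oars optional named list; each element a list with `center` and
#'   `semiaxes` in mm defining an ellipsoidal OAR.
#' @param padding_mm dose-grid padding beyond the brain surface (default 5).
#' @param combine dose combination mode, see [synthesize_dose()].
#' @param seed optional integer recorded in the phantom manifest.
#' @return An object of class `patient_phantom` with elements `grid`,
#'   `targets`, `dose`, `gtv_masks`, `ptv_masks`, `brain_mask`,
#'   `oar_masks`, `seed`.
#' @export
#' @examples
#' ph <- build_phantom(list(target_spec(c(0, 0, 0), 5)), brain_radius = 20)
#' volume_cc(ph$ptv_masks[[1]])
build_phantom <- function(targets, spacing = 1.25, brain_radius = 80,
                          isocenter = c(0, 0, 0), oars = NULL,
                          padding_mm = 5, combine = "sum", seed = NULL) {
  if (inherits(targets, "target_spec")) targets <- list(targets)
  stopifnot(length(targets) >= 1)
  ptv_reach <- vapply(targets, function(t) {
    sqrt(sum((t$center - isocenter)^2)) + t$gtv_radius + t$ptv_margin
  }, numeric(1))
  brain_radius <- max(brain_radius, max(ptv_reach) + 2 * spacing)
  extent <- brain_radius + padding_mm
  n <- 2L * as.integer(ceiling(extent / spacing)) + 1L  # odd: isocenter on a voxel centre
  grid <- grid_spec(n, spacing = spacing, isocenter = isocenter)

  gtv_masks <- lapply(seq_along(targets), function(i) {
    voxelize_sphere(grid, targets[[i]]$center, targets[[i]]$gtv_radius,
                    name = sprintf("GTV_%d", i))
  })
  ptv_masks <- lapply(seq_along(targets), function(i) {
    t <- targets[[i]]
    voxelize_sphere(grid, t$center, t$gtv_radius + t$ptv_margin,
                    name = sprintf("PTV_%d", i))
  })
  brain <- voxelize_sphere(grid, isocenter, brain_radius, name = "BRAIN")
  for (i in seq_along(targets)) {
    if (any(gtv_masks[[i]]$voxels & !ptv_masks[[i]]$voxels)) {
      stop(sprintf("GTV_%d is not contained in PTV_%d", i, i))
    }
    if (any(ptv_masks[[i]]$voxels & !brain$voxels)) {
      stop(sprintf("PTV_%d is not contained in the brain mask", i))
    }
  }
  oar_masks <- NULL
  if (!is.null(oars)) {
    oar_masks <- lapply(names(oars), function(nm) {
      voxelize_ellipsoid(grid, oars[[nm]]$center, oars[[nm]]$semiaxes,
                         name = nm)
    })
    names(oar_masks) <- names(oars)
  }
  structure(
    list(grid = grid, targets = targets,
         dose = synthesize_dose(grid, targets, combine = combine),
         gtv_masks = gtv_masks, ptv_masks = ptv_masks,
         brain_mask = brain, oar_masks = oar_masks, seed = seed),
    class = "patient_phantom"
  )
}

#' @export
print.patient_phantom <- function(x, ...) {
  cat(sprintf("<patient_phantom> %d target(s), brain %.1f cc, grid %s\n",
              length(x$targets), volume_cc(x$brain_mask),
              paste(x$grid$shape, collapse = " x ")))
  invisible(x)
}

#' Generate a synthetic cohort of patient phantoms
#'
#' @param config list (or path to a YAML/JSON file, see
#'   [read_cohort_config()]) with keys `n_patients`, `lesion_counts`
#'   (vector recycled over patients), `gtv_cc_range`, `distance_cm_range`,
#'   `spacing_mm`, `prescription_gy`, `idl_fraction`,
#'   `boundary_min_dose_gy`, `falloff_gradient_gy_per_mm`,
#'   `brain_radius_mm`, `seed`.  Missing keys fall back to the study-like
#'   defaults.
#' @return List of [build_phantom()] objects.
#' @export
generate_cohort <- function(config = list()) {
  if (is.character(config)) config <- read_cohort_config(config)
  dflt <- list(n_patients = 3, lesion_counts = c(2, 5, 8),
               gtv_cc_range = c(0.02, 11.5), distance_cm_range = c(2.2, 8.9),
               spacing_mm = 1.25, prescription_gy = 20, idl_fraction = 0.75,
               boundary_min_dose_gy = 19.2, falloff_gradient_gy_per_mm = 3.3,
               ptv_margin_mm = 1.0, brain_radius_mm = 80, seed = 1L)
  cfg <- utils::modifyList(dflt, config)
  counts <- rep_len(cfg$lesion_counts, cfg$n_patients)
  lapply(seq_len(cfg$n_patients), function(p) {
    seed_p <- cfg$seed + p - 1L
    specs <- sample_cohort_geometry(
      counts[p], seed = seed_p,
      cohort_ranges = list(gtv_cc = cfg$gtv_cc_range,
                           distance_cm = cfg$distance_cm_range),
      spacing_mm = cfg$spacing_mm,
      ptv_margin = cfg$ptv_margin_mm,
      prescription = cfg$prescription_gy,
      idl_fraction = cfg$idl_fraction,
      boundary_min_dose = cfg$boundary_min_dose_gy,
      falloff_gradient = cfg$falloff_gradient_gy_per_mm)
    build_phantom(specs, spacing = cfg$spacing_mm,
                  brain_radius = cfg$brain_radius_mm, seed = seed_p)
  })
}

#' Read a cohort configuration file
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file with the keys documented
#'   in [generate_cohort()].
#' @return A named list.
#' @export
read_cohort_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

#' Write / read a phantom to a patient directory
#'
#' Serialization format (documented contract): `manifest.json` carries the
#' grid spec, target specs and seed as plain JSON; `arrays.rds` is a base-R
#' `saveRDS` (version 3, xz-free default gzip) list with the dose array and
#' the logical mask arrays, keyed `dose`, `gtvs`, `ptvs`, `brain`, `oars`.
#'
#' @param phantom a [build_phantom()] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly (`write_phantom`); the phantom (`read_phantom`).
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "patient_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    grid = phantom$grid[c("shape", "spacing", "origin", "isocenter")],
    targets = lapply(phantom$targets, unclass),
    seed = phantom$seed,
    oar_names = names(phantom$oar_masks))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  arrays <- list(
    dose = phantom$dose$values,
    gtvs = lapply(phantom$gtv_masks, `[[`, "voxels"),
    ptvs = lapply(phantom$ptv_masks, `[[`, "voxels"),
    brain = phantom$brain_mask$voxels,
    oars = lapply(phantom$oar_masks, `[[`, "voxels"))
  saveRDS(arrays, file.path(dir, "arrays.rds"))
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  arrays <- readRDS(file.path(dir, "arrays.rds"))
  grid <- grid_spec(man$grid$shape, man$grid$spacing, man$grid$origin,
                    man$grid$isocenter)
  targets <- lapply(seq_len(nrow(man$targets)), function(i) {
    r <- man$targets[i, ]
    target_spec(unlist(r$center), r$gtv_radius, r$ptv_margin,
                r$prescription, r$idl_fraction, r$boundary_min_dose,
                r$falloff_gradient)
  })
  oar_masks <- NULL
  if (length(arrays$oars)) {
    oar_masks <- lapply(seq_along(arrays$oars), function(i) {
      structure_mask(arrays$oars[[i]], grid, name = man$oar_names[i])
    })
    names(oar_masks) <- man$oar_names
  }
  structure(
    list(grid = grid, targets = targets,
         dose = dose_grid(arrays$dose, grid),
         gtv_masks = lapply(seq_along(arrays$gtvs), function(i) {
           structure_mask(arrays$gtvs[[i]], grid, sprintf("GTV_%d", i))
         }),
         ptv_masks = lapply(seq_along(arrays$ptvs), function(i) {
           structure_mask(arrays$ptvs[[i]], grid, sprintf("PTV_%d", i))
         }),
         brain_mask = structure_mask(arrays$brain, grid, "BRAIN"),
         oar_masks = oar_masks, seed = man$seed),
    class = "patient_phantom"
  )
}
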