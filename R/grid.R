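#' Regular 3-D dose-grid geometry
#'
#' A `grid_spec` describes the voxel lattice shared by dose grids and
#' structure masks: voxel counts, isotropic or anisotropic spacing in mm,
#' the patient-space position of the centre of voxel `(1,1,1)`, and the
#' plan isocenter.  All package coordinates are patient-space millimetres;
#' nothing forces the isocenter onto the grid origin.
#'
#' @param shape integer vector of voxel counts per axis (x, y, z); a single
#'   value is recycled to all three axes.
#' @param spacing voxel size in mm per axis (default 1.25 mm isotropic, the
#'   finest calculation grid used for the plans the phantom emulates).
#' @param origin mm coordinates of the centre of voxel `(1,1,1)`.  Default
#'   centres the grid on `isocenter`.
#' @param isocenter mm coordinates of the plan isocenter; must lie inside
#'   the grid bounding box.
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' g <- grid_spec(41, spacing = 1.25)
#' g$isocenter
grid_spec <- function(shape, spacing = 1.25, origin = NULL,
                      isocenter = c(0, 0, 0)) {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, length(spacing) == 3L,
            length(isocenter) == 3L, all(is.finite(spacing)),
            all(shape >= 1L))
  if (any(spacing <= 0)) {
    stop("grid spacing must be > 0 on every axis")
  }
  if (is.null(origin)) {
    origin <- isocenter - (shape - 1L) * spacing / 2
  }
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  g <- structure(
    list(shape = shape, spacing = as.numeric(spacing),
         origin = as.numeric(origin), isocenter = as.numeric(isocenter)),
    class = "grid_spec"
  )
  bb <- grid_bbox(g)
  if (any(isocenter < bb$lo) || any(isocenter > bb$hi)) {
    stop("isocenter lies outside the grid bounding box")
  }
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, spacing %s mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, isocenter (%s) mm\n",
              paste(format(x$origin), collapse = ", "),
              paste(format(x$isocenter), collapse = ", ")))
  invisible(x)
}

#' Voxel-centre coordinates along one axis
#'
#' @param grid a [grid_spec()].
#' @param axis axis index 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of mm coordinates of voxel centres.
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

# bounding box of the voxel volume (outer faces, not centres)
grid_bbox <- function(grid) {
  list(lo = grid$origin - grid$spacing / 2,
       hi = grid$origin + (grid$shape - 1L + 0.5) * grid$spacing)
}

#' Volume of one voxel in cc
#' @param grid a [grid_spec()].
#' @return Voxel volume in cubic centimetres.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

# squared-distance field from `center`, as an nx x ny x nz array
.dist2_field <- function(grid, center) {
  dx2 <- (axis_coords(grid, 1) - center[1])^2
  dy2 <- (axis_coords(grid, 2) - center[2])^2
  dz2 <- (axis_coords(grid, 3) - center[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

same_lattice <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Absorbed-dose grid
#'
#' A 3-D scalar field of absorbed dose in Gy on a [grid_spec()] lattice.
#'
#' @param values numeric 3-D array of dose in Gy; finite and non-negative.
#' @param grid the [grid_spec()] the values live on.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"), is.array(values),
            identical(dim(values), as.integer(grid$shape)))
  if (!all(is.finite(values))) stop("dose values must all be finite")
  if (any(values < 0)) stop("dose values must be non-negative")
  structure(list(values = values, grid = grid), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> max %.2f Gy on %d x %d x %d grid\n",
              max(x$values), x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

#' Binary structure mask
#'
#' A named boolean voxel mask (GTV, PTV, brain, OAR or isodose volume) on
#' the same lattice as the dose it is compared with.  Reported volume is
#' voxel count times voxel volume.
#'
#' @param voxels logical 3-D array of membership.
#' @param grid the [grid_spec()] the mask lives on.
#' @param name structure name (free text, preserved through DICOM export).
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(voxels, grid, name = "structure") {
  stopifnot(inherits(grid, "grid_spec"), is.array(voxels), is.logical(voxels),
            identical(dim(voxels), as.integer(grid$shape)))
  structure(list(name = name, voxels = voxels, grid = grid),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d voxels, %.3f cc\n",
              x$name, sum(x$voxels), volume_cc(x)))
  invisible(x)
}

#' Structure volume in cc
#'
#' @param mask a [structure_mask()].
#' @return Volume in cubic centimetres (voxel count x voxel volume).
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$voxels) * voxel_volume_cc(mask$grid)
}

# shared guard for set algebra: masks/doses must share one lattice exactly
.check_same_lattice <- function(a, b, what = "objects") {
  ga <- if (inherits(a, "grid_spec")) a else a$grid
  gb <- if (inherits(b, "grid_spec")) b else b$grid
  if (!same_lattice(ga, gb)) {
    stop(sprintf("%s are not on the same voxel lattice; resample first", what))
  }
  invisible(TRUE)
}
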