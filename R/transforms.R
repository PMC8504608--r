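#' Six-degree-of-freedom setup-error transform
#'
#' Rigid patient setup error about the plan isocenter: translations
#' `dx, dy, dz` in mm and rotations pitch (y-z plane, about x), roll
#' (x-z plane, about y) and yaw (x-y plane, about z) in degrees.  The
#' rotation is applied about `pivot` (the isocenter), then the
#' translation.  Angles are degrees in every interface; radians appear
#' only internally.
#'
#' The rotation composition order is fixed (default pitch, then roll,
#' then yaw, composed on world axes); at the clinically simulated <= 2
#' degrees the point-displacement difference between orders is below
#' 0.01 mm, but the order stays configurable for exactness.
#'
#' @param dx,dy,dz translations in mm.
#' @param pitch,roll,yaw rotations in degrees; |angle| <= 10 (guard far
#'   above the <= 2 degree study range).
#' @param pivot rotation pivot in mm (the isocenter).
#' @param order character permutation of `"pitch"`, `"roll"`, `"yaw"`
#'   giving the application order.
#' @return An object of class `transform6dof`.
#' @export
#' @examples
#' t <- transform6dof(dx = 2, yaw = 2)
#' build_matrix(t)
transform6dof <- function(dx = 0, dy = 0, dz = 0,
                          pitch = 0, roll = 0, yaw = 0,
                          pivot = c(0, 0, 0),
                          order = c("pitch", "roll", "yaw")) {
  ang <- c(pitch = pitch, roll = roll, yaw = yaw)
  if (any(abs(ang) > 10)) {
    stop("rotations beyond 10 degrees are outside the supported guard range")
  }
  stopifnot(length(pivot) == 3L, all(is.finite(c(dx, dy, dz, ang, pivot))))
  order <- match.arg(order, c("pitch", "roll", "yaw"), several.ok = TRUE)
  if (length(order) != 3L || anyDuplicated(order)) {
    stop("order must be a permutation of pitch, roll, yaw")
  }
  structure(
    list(dx = dx, dy = dy, dz = dz, pitch = pitch, roll = roll, yaw = yaw,
         pivot = as.numeric(pivot), order = order),
    class = "transform6dof"
  )
}

#' @export
print.transform6dof <- function(x, ...) {
  cat(sprintf(
    "<transform6dof> t = (%.3g, %.3g, %.3g) mm, (pitch, roll, yaw) = (%.3g, %.3g, %.3g) deg\n",
    x$dx, x$dy, x$dz, x$pitch, x$roll, x$yaw))
  cat(sprintf("  pivot (%s) mm, order %s\n",
              paste(format(x$pivot), collapse = ", "),
              paste(x$order, collapse = " -> ")))
  invisible(x)
}

# elementary rotation matrices; angle in degrees
.rot3 <- function(axis, deg) {
  a <- deg * pi / 180
  c1 <- cos(a); s1 <- sin(a)
  switch(axis,
         pitch = matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3),   # about x
         roll  = matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3),   # about y
         yaw   = matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3))   # about z
}

#' Homogeneous 4x4 matrix of a setup-error transform
#'
#' Maps patient-space points x to `R (x - pivot) + pivot + t` where R is
#' the composed rotation and t the translation vector.
#'
#' @param t a [transform6dof()] (a 4x4 matrix is passed through).
#' @return A 4x4 homogeneous transform with an orthonormal rotation block.
#' @export
build_matrix <- function(t) {
  if (is.matrix(t)) {
    stopifnot(identical(dim(t), c(4L, 4L)))
    return(t)
  }
  stopifnot(inherits(t, "transform6dof"))
  R <- diag(3)
  for (ax in t$order) R <- .rot3(ax, t[[ax]]) %*% R
  tr <- c(t$dx, t$dy, t$dz)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t$pivot - R %*% t$pivot + tr
  M
}

#' Inverse of a setup-error transform
#'
#' @param t a [transform6dof()] or 4x4 homogeneous matrix.
#' @return The 4x4 homogeneous inverse, usable anywhere a transform is
#'   accepted.
#' @export
invert_transform <- function(t) {
  M <- build_matrix(t)
  R <- M[1:3, 1:3]
  Minv <- diag(4)
  Minv[1:3, 1:3] <- t(R)
  Minv[1:3, 4] <- -t(R) %*% M[1:3, 4]
  Minv
}

#' Apply a transform to a matrix of points
#'
#' @param t a [transform6dof()] or 4x4 matrix.
#' @param pts numeric matrix with one mm point per row (n x 3).
#' @return Transformed points, n x 3.
#' @export
transform_points <- function(t, pts) {
  M <- build_matrix(t)
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts %*% t(M[1:3, 1:3]), 2, M[1:3, 4], "+")
}

#' Build the coupled setup-error vector of a sweep point
#'
#' Every translational component gets |value| = `magnitude_mm` and every
#' rotational component |value| = `magnitude_deg`, mirroring the
#' systematically simulated "x mm / x degrees in all six degrees of
#' freedom" error settings.  Signs are all positive by default (flagged
#' as an assumption in reports), fixed from a +/-1 vector, or drawn
#' reproducibly from `seed`.
#'
#' @param magnitude_mm translation magnitude per axis in mm (>= 0).
#' @param magnitude_deg rotation magnitude per axis in degrees (>= 0).
#' @param signs `"all_positive"`, `"random"`, or a numeric vector of six
#'   values in {-1, +1} ordered (dx, dy, dz, pitch, roll, yaw).
#' @param seed integer seed, required for `signs = "random"`.
#' @param pivot rotation pivot in mm.
#' @return A [transform6dof()].
#' @export
error_vector <- function(magnitude_mm, magnitude_deg,
                         signs = "all_positive", seed = NULL,
                         pivot = c(0, 0, 0)) {
  stopifnot(magnitude_mm >= 0, magnitude_deg >= 0)
  if (is.character(signs)) {
    signs <- match.arg(signs, c("all_positive", "random"))
    if (signs == "all_positive") {
      s <- rep(1, 6)
    } else {
      if (is.null(seed)) stop("signs = 'random' requires a seed")
      s <- with_seed(seed, sample(c(-1, 1), 6, replace = TRUE))
    }
  } else {
    stopifnot(length(signs) == 6L, all(abs(signs) == 1))
    s <- signs
  }
  transform6dof(dx = s[1] * magnitude_mm, dy = s[2] * magnitude_mm,
                dz = s[3] * magnitude_mm,
                pitch = s[4] * magnitude_deg, roll = s[5] * magnitude_deg,
                yaw = s[6] * magnitude_deg, pivot = pivot)
}

# vectorised trilinear interpolation of `values` (3-D array on `grid`) at
# mm points (qx, qy, qz); out-of-grid samples get `fill` and are flagged
.interp_trilinear <- function(values, grid, qx, qy, qz, fill = 0) {
  n <- grid$shape
  u <- (qx - grid$origin[1]) / grid$spacing[1] + 1
  v <- (qy - grid$origin[2]) / grid$spacing[2] + 1
  w <- (qz - grid$origin[3]) / grid$spacing[3] + 1
  inside <- u >= 1 & u <= n[1] & v >= 1 & v <= n[2] & w >= 1 & w <= n[3]
  i0 <- pmin(pmax(floor(u), 1), n[1] - 1L)
  j0 <- pmin(pmax(floor(v), 1), n[2] - 1L)
  k0 <- pmin(pmax(floor(w), 1), n[3] - 1L)
  fx <- u - i0; fy <- v - j0; fz <- w - k0
  nx <- n[1]; nxy <- n[1] * n[2]
  ii <- i0 + (j0 - 1) * nx + (k0 - 1) * nxy
  out <-
    (1 - fx) * (1 - fy) * (1 - fz) * values[ii] +
    fx       * (1 - fy) * (1 - fz) * values[ii + 1] +
    (1 - fx) * fy       * (1 - fz) * values[ii + nx] +
    fx       * fy       * (1 - fz) * values[ii + nx + 1] +
    (1 - fx) * (1 - fy) * fz       * values[ii + nxy] +
    fx       * (1 - fy) * fz       * values[ii + nxy + 1] +
    (1 - fx) * fy       * fz       * values[ii + nxy + nx] +
    fx       * fy       * fz       * values[ii + nxy + nx + 1]
  out[!inside] <- fill
  list(values = out, outside = !inside)
}

#' Perturb a dose grid by a rigid setup error
#'
#' Resamples the dose at inverse-transformed voxel-centre coordinates by
#' trilinear interpolation: the structures stay fixed while the dose
#' cloud moves relative to the anatomy, which is equivalent to a rigid
#' patient setup error with the plan unchanged apart from the isocenter
#' shift.  Samples falling outside the grid are filled with 0 Gy and
#' counted in the `clipped_fraction` attribute of the result; a warning
#' is raised when that fraction (restricted to `within` when given,
#' typically the brain mask) exceeds `clip_warn_fraction`.
#'
#' @param dose a [dose_grid()] with finite values.
#' @param t a [transform6dof()] or 4x4 homogeneous matrix.
#' @param within optional [structure_mask()] over which the clipping
#'   statistic is evaluated (default: whole grid).
#' @param clip_warn_fraction warning threshold for the clipped fraction
#'   (default 0.01).
#' @return A [dose_grid()] with attribute `clipped_fraction`.
#' @export
apply_setup_error <- function(dose, t, within = NULL,
                              clip_warn_fraction = 0.01) {
  stopifnot(inherits(dose, "dose_grid"))
  Minv <- invert_transform(t)
  g <- dose$grid
  xs <- axis_coords(g, 1); ys <- axis_coords(g, 2); zs <- axis_coords(g, 3)
  nx <- g$shape[1]; ny <- g$shape[2]; nz <- g$shape[3]
  X <- rep(xs, times = ny * nz)
  Y <- rep(rep(ys, each = nx), times = nz)
  Z <- rep(zs, each = nx * ny)
  A <- Minv[1:3, 1:3]; b <- Minv[1:3, 4]
  qx <- A[1, 1] * X + A[1, 2] * Y + A[1, 3] * Z + b[1]
  qy <- A[2, 1] * X + A[2, 2] * Y + A[2, 3] * Z + b[2]
  qz <- A[3, 1] * X + A[3, 2] * Y + A[3, 3] * Z + b[3]
  res <- .interp_trilinear(dose$values, g, qx, qy, qz, fill = 0)
  out <- dose_grid(array(pmax(res$values, 0), dim = g$shape), g)
  clipped <- if (!is.null(within)) {
    .check_same_lattice(dose, within, "dose and clipping mask")
    mean(res$outside[as.vector(within$voxels)])
  } else {
    mean(res$outside)
  }
  if (is.nan(clipped)) clipped <- 0
  attr(out, "clipped_fraction") <- clipped
  if (clipped > clip_warn_fraction) {
    warning(sprintf(
      "%.2f%% of evaluated voxels sampled outside the dose grid (0 Gy fill)",
      100 * clipped))
  }
  out
}
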