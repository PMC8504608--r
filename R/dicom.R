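# Minimal DICOM-RT reader/writer (explicit-VR little-endian only).
# Covers just the RT Dose and RT Structure Set subset this pipeline needs:
# axis-aligned dose grids with uniform frame spacing, and closed planar
# contours.  Not a general DICOM implementation.

.DCM_UID_ROOT <- "1.2.826.0.1.3680043.10.1457"  # free-use org root + suffix
.UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
.UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
.UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) {
  # length fields fit in a signed int for every object we write
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

.pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

.val_str <- function(s, pad = as.raw(0x20)) .pad_even(charToRaw(s), pad)
.val_ui <- function(s) .val_str(s, pad = as.raw(0x00))
.val_ds <- function(x) .val_str(paste(sprintf("%.8g", x), collapse = "\\"))
.val_is <- function(x) .val_str(paste(sprintf("%d", as.integer(x)),
                                      collapse = "\\"))
.val_us <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")

.elem <- function(group, element, vr, value) {
  head <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% .LONG_VRS) {
    c(head, as.raw(c(0, 0)), .u32(length(value)), value)
  } else {
    stopifnot(length(value) <= 65534)
    c(head, .u16(length(value)), value)
  }
}

.sq_item <- function(content) c(.u16(0xFFFE), .u16(0xE000),
                                .u32(length(content)), content)

.dcm_file <- function(path, sop_class, sop_instance, dataset) {
  meta <- c(
    .elem(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    .elem(0x0002, 0x0002, "UI", .val_ui(sop_class)),
    .elem(0x0002, 0x0003, "UI", .val_ui(sop_instance)),
    .elem(0x0002, 0x0010, "UI", .val_ui(.UID_EXPLICIT_LE)),
    .elem(0x0002, 0x0012, "UI", .val_ui(paste0(.DCM_UID_ROOT, ".1"))))
  bytes <- c(raw(128), charToRaw("DICM"),
             .elem(0x0002, 0x0000, "UL", .u32(length(meta))),
             meta, dataset)
  writeBin(bytes, path)
  invisible(path)
}

#' Write a dose grid as a DICOM RT Dose file
#'
#' Explicit-VR little-endian, 32-bit pixels, axis-aligned orientation.
#' Dose in Gy is quantised by `DoseGridScaling` chosen so the grid
#' maximum maps to the full 31-bit integer range.
#'
#' @param dose a [dose_grid()].
#' @param path output file path.
#' @param frame_of_reference_uid DICOM frame-of-reference UID shared with
#'   the matching structure set.
#' @param scaling dose-grid scaling in Gy per integer unit; default picks
#'   `max(dose) / (2^31 - 1)`.  (A zero value is written verbatim, which
#'   produces a file that readers must reject.)
#' @return `path`, invisibly.
#' @export
write_dicom_rtdose <- function(dose, path,
                               frame_of_reference_uid =
                                 paste0(.DCM_UID_ROOT, ".2"),
                               scaling = NULL) {
  stopifnot(inherits(dose, "dose_grid"))
  g <- dose$grid
  if (is.null(scaling)) {
    scaling <- max(dose$values) / (2^31 - 1)
    if (scaling == 0) scaling <- 1
  }
  px <- if (scaling == 0) {
    as.integer(array(0L, dim = g$shape))
  } else {
    as.integer(round(as.vector(dose$values) / scaling))
  }
  offsets <- (seq_len(g$shape[3]) - 1) * g$spacing[3]
  ds <- c(
    .elem(0x0008, 0x0016, "UI", .val_ui(.UID_RTDOSE)),
    .elem(0x0008, 0x0018, "UI", .val_ui(paste0(.DCM_UID_ROOT, ".3.1"))),
    .elem(0x0008, 0x0060, "CS", .val_str("RTDOSE")),
    .elem(0x0020, 0x0032, "DS", .val_ds(g$origin)),
    .elem(0x0020, 0x0037, "DS", .val_ds(c(1, 0, 0, 0, 1, 0))),
    .elem(0x0020, 0x0052, "UI", .val_ui(frame_of_reference_uid)),
    .elem(0x0028, 0x0002, "US", .val_us(1)),
    .elem(0x0028, 0x0004, "CS", .val_str("MONOCHROME2")),
    .elem(0x0028, 0x0008, "IS", .val_is(g$shape[3])),
    .elem(0x0028, 0x0010, "US", .val_us(g$shape[2])),   # rows = y
    .elem(0x0028, 0x0011, "US", .val_us(g$shape[1])),   # cols = x
    .elem(0x0028, 0x0030, "DS", .val_ds(c(g$spacing[2], g$spacing[1]))),
    .elem(0x0028, 0x0100, "US", .val_us(32)),
    .elem(0x0028, 0x0101, "US", .val_us(32)),
    .elem(0x0028, 0x0102, "US", .val_us(31)),
    .elem(0x0028, 0x0103, "US", .val_us(0)),
    .elem(0x3004, 0x0002, "CS", .val_str("GY")),
    .elem(0x3004, 0x0004, "CS", .val_str("PHYSICAL")),
    .elem(0x3004, 0x000A, "CS", .val_str("PLAN")),
    .elem(0x3004, 0x000C, "DS", .val_ds(offsets)),
    .elem(0x3004, 0x000E, "DS",
          .val_str(sprintf("%.10e", scaling))),
    .elem(0x7FE0, 0x0010, "OW",
          writeBin(px, raw(), size = 4, endian = "little")))
  .dcm_file(path, .UID_RTDOSE, paste0(.DCM_UID_ROOT, ".3.1"), ds)
}

#' Write structures as a DICOM RT Structure Set
#'
#' @param structures named list; each element is a list of closed planar
#'   contours, each an n x 3 matrix of mm coordinates with constant z.
#' @param path output file path.
#' @param frame_of_reference_uid frame-of-reference UID matching the dose.
#' @return `path`, invisibly.
#' @export
write_dicom_rtstruct <- function(structures, path,
                                 frame_of_reference_uid =
                                   paste0(.DCM_UID_ROOT, ".2")) {
  stopifnot(is.list(structures), length(structures) >= 1,
            !is.null(names(structures)))
  roi_items <- lapply(seq_along(structures), function(i) {
    .sq_item(c(
      .elem(0x3006, 0x0022, "IS", .val_is(i)),
      .elem(0x3006, 0x0024, "UI", .val_ui(frame_of_reference_uid)),
      .elem(0x3006, 0x0026, "LO", .val_str(names(structures)[i]))))
  })
  contour_items <- lapply(seq_along(structures), function(i) {
    contours <- structures[[i]]
    inner <- lapply(contours, function(pts) {
      pts <- matrix(as.numeric(pts), ncol = 3)
      .sq_item(c(
        .elem(0x3006, 0x0042, "CS", .val_str("CLOSED_PLANAR")),
        .elem(0x3006, 0x0046, "IS", .val_is(nrow(pts))),
        .elem(0x3006, 0x0050, "DS", .val_ds(as.vector(t(pts))))))
    })
    .sq_item(c(
      .elem(0x3006, 0x0040, "SQ", do.call(c, inner)),
      .elem(0x3006, 0x0084, "IS", .val_is(i))))
  })
  ds <- c(
    .elem(0x0008, 0x0016, "UI", .val_ui(.UID_RTSTRUCT)),
    .elem(0x0008, 0x0018, "UI", .val_ui(paste0(.DCM_UID_ROOT, ".4.1"))),
    .elem(0x0008, 0x0060, "CS", .val_str("RTSTRUCT")),
    .elem(0x3006, 0x0002, "SH", .val_str("icksim")),
    .elem(0x3006, 0x0020, "SQ", do.call(c, roi_items)),
    .elem(0x3006, 0x0039, "SQ", do.call(c, contour_items)))
  .dcm_file(path, .UID_RTSTRUCT, paste0(.DCM_UID_ROOT, ".4.1"), ds)
}

# ---- reading -------------------------------------------------------------

.rd_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
.rd_u32 <- function(raw, pos) {
  as.integer(raw[pos]) + 256 * as.integer(raw[pos + 1L]) +
    65536 * as.integer(raw[pos + 2L]) + 16777216 * as.integer(raw[pos + 3L])
}

# parse an explicit-VR little-endian element stream in raw[pos..end];
# returns list(elements = named list(tag -> list(vr, value)), pos)
.parse_dataset <- function(raw, pos, end) {
  out <- list()
  while (pos <= end) {
    group <- .rd_u16(raw, pos)
    element <- .rd_u16(raw, pos + 2L)
    if (group == 0xFFFE && element == 0xE00D) {  # item delimitation
      pos <- pos + 8L
      break
    }
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- .rd_u32(raw, pos + 8L)
      vpos <- pos + 12L
    } else {
      len <- .rd_u16(raw, pos + 6L)
      vpos <- pos + 8L
    }
    tag <- sprintf("%04X%04X", group, element)
    if (vr == "SQ") {
      items <- list()
      if (len == -1 || len == 4294967295) {  # undefined length
        p <- vpos
        repeat {
          g2 <- .rd_u16(raw, p); e2 <- .rd_u16(raw, p + 2L)
          if (g2 == 0xFFFE && e2 == 0xE0DD) { p <- p + 8L; break }
          stopifnot(g2 == 0xFFFE, e2 == 0xE000)
          ilen <- .rd_u32(raw, p + 4L)
          if (ilen == -1 || ilen == 4294967295) {
            r <- .parse_dataset(raw, p + 8L, end)
          } else {
            r <- .parse_dataset(raw, p + 8L, p + 7L + ilen)
          }
          items[[length(items) + 1L]] <- r$elements
          p <- r$pos
        }
        pos <- p
      } else {
        p <- vpos
        while (p < vpos + len) {
          stopifnot(.rd_u16(raw, p) == 0xFFFE, .rd_u16(raw, p + 2L) == 0xE000)
          ilen <- .rd_u32(raw, p + 4L)
          r <- .parse_dataset(raw, p + 8L, p + 7L + ilen)
          items[[length(items) + 1L]] <- r$elements
          p <- r$pos
        }
        pos <- vpos + len
      }
      out[[tag]] <- list(vr = vr, items = items)
    } else {
      out[[tag]] <- list(vr = vr,
                         value = raw[seq.int(vpos, length.out = len)])
      pos <- vpos + len
    }
  }
  list(elements = out, pos = pos)
}

.read_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM") {
    stop(sprintf("'%s' is not a DICOM file", path))
  }
  .parse_dataset(raw, 133L, length(raw))$elements
}

.dcm_str <- function(ds, tag) {
  e <- ds[[tag]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$value[e$value != as.raw(0)]))
}
.dcm_ds <- function(ds, tag) {
  s <- .dcm_str(ds, tag)
  if (is.null(s)) NULL else as.numeric(strsplit(s, "\\\\")[[1]])
}
.dcm_us <- function(ds, tag) {
  e <- ds[[tag]]
  if (is.null(e)) NULL else readBin(e$value, "integer", size = 2,
                                    endian = "little", signed = FALSE)
}

#' Read a DICOM RT Dose file
#'
#' Supports the explicit-VR little-endian, axis-aligned, uniform-frame
#' subset written by [write_dicom_rtdose()] (and by typical planning-
#' system exports of the same form).
#'
#' @param path RT Dose file.
#' @return A [dose_grid()] with attribute `frame_of_reference_uid`.
#' @export
read_dicom_rtdose <- function(path) {
  ds <- .read_dicom(path)
  if (!identical(.dcm_str(ds, "00080060"), "RTDOSE")) {
    stop("not an RT Dose file")
  }
  scaling <- .dcm_ds(ds, "3004000E")
  if (is.null(scaling) || length(scaling) != 1 || !is.finite(scaling) ||
      scaling <= 0) {
    stop("missing or invalid DoseGridScaling")
  }
  orient <- .dcm_ds(ds, "00200037")
  if (!is.null(orient) && max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-6) {
    stop("only axis-aligned dose grids are supported")
  }
  nx <- .dcm_us(ds, "00280011")
  ny <- .dcm_us(ds, "00280010")
  nz <- as.integer(.dcm_ds(ds, "00280008"))
  origin <- .dcm_ds(ds, "00200032")
  ps <- .dcm_ds(ds, "00280030")          # (row spacing = y, col spacing = x)
  offs <- .dcm_ds(ds, "3004000C")
  dz <- if (nz > 1) diff(offs) else 1.25
  if (nz > 1 && (max(dz) - min(dz)) > 1e-6) {
    stop("non-uniform frame spacing is not supported")
  }
  dz <- if (nz > 1) dz[1] else dz
  grid <- grid_spec(c(nx, ny, nz), spacing = c(ps[2], ps[1], dz),
                    origin = origin + c(0, 0, offs[1]),
                    isocenter = origin + c(0, 0, offs[1]) +
                      (c(nx, ny, nz) - 1) * c(ps[2], ps[1], dz) / 2)
  px <- readBin(ds[["7FE00010"]]$value, "integer", n = nx * ny * nz,
                size = 4, endian = "little")
  dose <- dose_grid(array(px * scaling, dim = c(nx, ny, nz)), grid)
  attr(dose, "frame_of_reference_uid") <- .dcm_str(ds, "00200052")
  dose
}

#' Read a DICOM RT Structure Set and voxelize it onto a grid
#'
#' Contours are rasterized slice by slice with point-in-polygon tests of
#' the voxel centres (matching the voxel-centre membership convention of
#' the synthetic masks).
#'
#' @param path RT Structure Set file.
#' @param grid target [grid_spec()] lattice (usually the dose grid).
#' @return Named list of [structure_mask()] objects with attribute
#'   `frame_of_reference_uid`.
#' @export
read_dicom_rtstruct <- function(path, grid) {
  ds <- .read_dicom(path)
  if (!identical(.dcm_str(ds, "00080060"), "RTSTRUCT")) {
    stop("not an RT Structure Set file")
  }
  rois <- ds[["30060020"]]$items
  names_by_number <- list()
  for_uid <- NULL
  for (it in rois) {
    num <- .dcm_str(it, "30060022")
    names_by_number[[num]] <- .dcm_str(it, "30060026")
    for_uid <- .dcm_str(it, "30060024")
  }
  xs <- axis_coords(grid, 1)
  ys <- axis_coords(grid, 2)
  zs <- axis_coords(grid, 3)
  masks <- list()
  for (it in ds[["30060039"]]$items) {
    num <- .dcm_str(it, "30060084")
    nm <- names_by_number[[num]]
    vox <- array(FALSE, dim = grid$shape)
    for (ct in it[["30060040"]]$items) {
      pts <- matrix(.dcm_ds(ct, "30060050"), ncol = 3, byrow = TRUE)
      k <- which.min(abs(zs - pts[1, 3]))
      if (abs(zs[k] - pts[1, 3]) > grid$spacing[3] / 2 + 1e-6) next
      xi <- which(xs >= min(pts[, 1]) - grid$spacing[1] &
                    xs <= max(pts[, 1]) + grid$spacing[1])
      yi <- which(ys >= min(pts[, 2]) - grid$spacing[2] &
                    ys <= max(pts[, 2]) + grid$spacing[2])
      if (!length(xi) || !length(yi)) next
      qp <- cbind(rep(xs[xi], times = length(yi)),
                  rep(ys[yi], each = length(xi)))
      bnd <- rbind(pts[, 1:2], pts[1, 1:2])
      inside <- mgcv::in.out(bnd, qp)
      vox[xi, yi, k] <- vox[xi, yi, k] |
        matrix(inside, length(xi), length(yi))
    }
    masks[[nm]] <- structure_mask(vox, grid, name = nm)
  }
  attr(masks, "frame_of_reference_uid") <- for_uid
  masks
}

#' Import a DICOM-RT plan export as a patient phantom
#'
#' Reads an RT Dose and an RT Structure Set referencing a common frame of
#' reference, converts dose to Gy via the grid scaling attribute, and
#' voxelizes each contoured structure onto the dose lattice.  Structure
#' names are preserved; masks named `PTV*` become the per-target PTV
#' masks, a mask named `BRAIN` (case-insensitive) becomes the brain mask,
#' and everything else is kept as an OAR mask.  No target specifications
#' are attached (real plans carry none).
#'
#' @param rtdose_path RT Dose file.
#' @param rtstruct_path RT Structure Set file.
#' @return A `patient_phantom` (with empty `targets`).
#' @export
import_dicom_rt <- function(rtdose_path, rtstruct_path) {
  dose <- read_dicom_rtdose(rtdose_path)
  masks <- read_dicom_rtstruct(rtstruct_path, dose$grid)
  for_dose <- attr(dose, "frame_of_reference_uid")
  for_struct <- attr(masks, "frame_of_reference_uid")
  if (!is.null(for_dose) && !is.null(for_struct) &&
      !identical(for_dose, for_struct)) {
    stop("RT Dose and RT Structure Set reference different frames of reference")
  }
  nm <- names(masks)
  is_ptv <- grepl("^PTV", nm, ignore.case = TRUE)
  is_gtv <- grepl("^GTV", nm, ignore.case = TRUE)
  is_brain <- grepl("^BRAIN$", nm, ignore.case = TRUE)
  brain <- if (any(is_brain)) masks[[which(is_brain)[1]]] else NULL
  structure(
    list(grid = dose$grid, targets = list(), dose = dose,
         gtv_masks = unname(masks[is_gtv]), ptv_masks = unname(masks[is_ptv]),
         brain_mask = brain,
         oar_masks = masks[!(is_ptv | is_gtv | is_brain)],
         seed = NULL),
    class = "patient_phantom"
  )
}

# closed planar circle contours of a sphere, one per intersecting slice
.sphere_contours <- function(center, radius, grid, n_points = 48) {
  zs <- axis_coords(grid, 3)
  ks <- which(abs(zs - center[3]) < radius)
  theta <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  lapply(ks, function(k) {
    r <- sqrt(radius^2 - (zs[k] - center[3])^2)
    cbind(center[1] + r * cos(theta), center[2] + r * sin(theta), zs[k])
  })
}

#' Export a phantom as DICOM-RT Dose and Structure Set files
#'
#' Writes `dose.dcm` and `struct.dcm` into `dir`; structures are the
#' per-target PTVs and the brain sphere, with circle contours generated
#' analytically per slice.
#'
#' @param phantom a [build_phantom()] phantom (spherical targets).
#' @param dir output directory (created if missing).
#' @return Named character vector with paths `rtdose` and `rtstruct`.
#' @export
export_dicom_rt <- function(phantom, dir) {
  stopifnot(inherits(phantom, "patient_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dose_path <- file.path(dir, "dose.dcm")
  struct_path <- file.path(dir, "struct.dcm")
  write_dicom_rtdose(phantom$dose, dose_path)
  structures <- list()
  for (i in seq_along(phantom$targets)) {
    t <- phantom$targets[[i]]
    structures[[sprintf("PTV_%d", i)]] <-
      .sphere_contours(t$center, t$gtv_radius + t$ptv_margin, phantom$grid)
  }
  brain_r <- radius_from_cc(volume_cc(phantom$brain_mask))
  structures[["BRAIN"]] <-
    .sphere_contours(phantom$grid$isocenter, brain_r, phantom$grid)
  write_dicom_rtstruct(structures, struct_path)
  c(rtdose = dose_path, rtstruct = struct_path)
}
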