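# Core image containers, contour geometry and NIfTI round-trip I/O.
#
# Conventions used throughout the package:
#   * volumes are indexed (slice, row, col), 1-based;
#   * pixel centers sit at integer coordinates 1..nrow / 1..ncol, so the
#     physical footprint of a slice spans [0.5, n + 0.5] in pixel units;
#   * contour vertices and ROI centers are (row, col) in those pixel units,
#     fractional values allowed;
#   * the JSON interchange files store 0-based coordinates (see
#     read_contours/write_contours), converted on the way in/out.

#' Construct a voxel grid
#'
#' A 3-D scalar image with per-axis physical spacing and a modality tag.
#' MR volumes hold arbitrary signal units and must be non-negative; CT
#' volumes hold Hounsfield units and may be negative. The inter-slice
#' sampling distance ("effective slice spacing") is
#' `slice_thickness_mm + slice_gap_mm`, matching a gapped 2-D acquisition
#' where each slice represents its full slab.
#'
#' @param values 3-D numeric array indexed (slice, row, col); all finite.
#' @param pixel_spacing_mm length-2 numeric, in-plane (row, col) spacing in mm.
#' @param slice_thickness_mm acquired slice thickness in mm.
#' @param slice_gap_mm inter-slice gap in mm (>= 0).
#' @param modality `"MR"` or `"CT"`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, pixel_spacing_mm = c(1.6, 1.6),
                       slice_thickness_mm = 8, slice_gap_mm = 2,
                       modality = c("MR", "CT")) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array indexed (slice, row, col)")
  if (length(values) == 0L) stop("empty 0-voxel grid")
  if (!all(is.finite(values))) stop("all voxel values must be finite")
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
    stop("'pixel_spacing_mm' must be two positive values (row, col)")
  if (slice_thickness_mm <= 0) stop("'slice_thickness_mm' must be > 0")
  if (slice_gap_mm < 0) stop("'slice_gap_mm' must be >= 0")
  if (modality == "MR" && any(values < 0))
    stop("MR volumes must be non-negative")
  structure(
    list(values = values,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         slice_gap_mm = as.numeric(slice_gap_mm),
         modality = modality),
    class = "voxel_grid")
}

#' Effective inter-slice spacing (thickness + gap), mm
#' @param grid a [voxel_grid].
#' @export
slice_spacing <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  grid$slice_thickness_mm + grid$slice_gap_mm
}

#' Physical volume of one voxel in mm^3 (using effective slice spacing)
#' @param grid a [voxel_grid].
#' @export
voxel_volume_mm3 <- function(grid) {
  prod(grid$pixel_spacing_mm) * slice_spacing(grid)
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid %s> %d slices x %d x %d, in-plane %.3g x %.3g mm, slice %g + %g mm gap\n",
              x$modality, d[1], d[2], d[3],
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm, x$slice_gap_mm))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

# ---- planar contours -------------------------------------------------------

#' Closed planar contour on one slice
#'
#' An ordered, implicitly closed polygon delimiting an analysis region
#' (e.g. the manually traced intra-thoracic border). The polygon must be
#' simple (no self-intersection) and enclose a positive area.
#'
#' @param slice_index 1-based slice index.
#' @param vertices n x 2 matrix of (row, col) pixel coordinates, n >= 3.
#' @return An object of class `planar_contour`.
#' @export
planar_contour <- function(slice_index, vertices) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("'vertices' must be an n x 2 numeric matrix with n >= 3")
  if (!all(is.finite(vertices))) stop("contour vertices must be finite")
  if (.polygon_self_intersects(vertices)) stop("self-intersecting polygon")
  if (abs(.polygon_area(vertices)) <= 0) stop("contour encloses zero area")
  structure(list(slice_index = as.integer(slice_index),
                 vertices = unname(vertices)),
            class = "planar_contour")
}

#' @export
print.planar_contour <- function(x, ...) {
  cat(sprintf("<planar_contour> slice %d, %d vertices, area %.4g px^2\n",
              x$slice_index, nrow(x$vertices), abs(.polygon_area(x$vertices))))
  invisible(x)
}

# Shoelace area in pixel^2 (signed).
.polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  sum(v[j, 1] * v[, 2] - v[, 1] * v[j, 2]) / 2
}

# Proper-crossing test between non-adjacent edges; shared vertices between
# adjacent edges are not intersections.
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      if (k == i + 1L || (i == 1L && k == n)) next
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[k, 1:2]; d <- seg[k, 3:4]
      o1 <- orient(a[1], a[2], b[1], b[2], c[1], c[2])
      o2 <- orient(a[1], a[2], b[1], b[2], d[1], d[2])
      o3 <- orient(c[1], c[2], d[1], d[2], a[1], a[2])
      o4 <- orient(c[1], c[2], d[1], d[2], b[1], b[2])
      if (o1 != o2 && o3 != o4) return(TRUE)
    }
  }
  FALSE
}

# Even-odd point-in-polygon for vectors of points. The tested row is offset
# by +1e-9 so pixel centers never sit exactly on a horizontal edge, making
# the rule deterministic and independent of vertex orientation.
.point_in_polygon <- function(r, c, verts) {
  rr <- r + 1e-9
  n <- nrow(verts)
  inside <- logical(length(rr))
  j <- n
  for (i in seq_len(n)) {
    r1 <- verts[i, 1]; c1 <- verts[i, 2]
    r2 <- verts[j, 1]; c2 <- verts[j, 2]
    crosses <- (r1 > rr) != (r2 > rr)
    if (any(crosses)) {
      cint <- c1 + (rr - r1) * (c2 - c1) / (r2 - r1)
      flip <- crosses & (c < cint)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

# ---- binary masks ----------------------------------------------------------

#' Binary mask congruent with a voxel grid
#' @param values 3-D logical array.
#' @param provenance free-text label of the operation that produced it.
#' @export
binary_mask <- function(values, provenance = "") {
  if (!is.array(values) || length(dim(values)) != 3L || !is.logical(values))
    stop("'values' must be a 3-D logical array")
  structure(list(values = values, provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s, %d of %d voxels true (%s)\n",
              paste(dim(x$values), collapse = "x"),
              sum(x$values), length(x$values),
              if (nzchar(x$provenance)) x$provenance else "unlabelled"))
  invisible(x)
}

.check_congruent <- function(a, b, what = "masks") {
  da <- if (inherits(a, c("binary_mask", "voxel_grid"))) dim(a$values) else dim(a)
  db <- if (inherits(b, c("binary_mask", "voxel_grid"))) dim(b$values) else dim(b)
  if (!identical(da, db)) stop("shape mismatch between ", what)
  invisible(TRUE)
}

#' Rasterize a closed contour onto a grid
#'
#' Marks exactly the pixels whose centers lie inside the polygon, on the
#' contour's slice only. A pixel belongs to the region iff its center is
#' inside under the even-odd rule; centers falling exactly on an edge are
#' resolved by a fixed +1e-9 row offset, so the result is deterministic and
#' identical for reversed vertex order.
#'
#' @param contour a [planar_contour].
#' @param grid_shape integer length-3, (slices, rows, cols).
#' @return A [binary_mask].
#' @export
rasterize_contour <- function(contour, grid_shape) {
  stopifnot(inherits(contour, "planar_contour"), length(grid_shape) == 3L)
  grid_shape <- as.integer(grid_shape)
  s <- contour$slice_index
  if (s < 1L || s > grid_shape[1])
    stop("contour slice index out of bounds")
  v <- contour$vertices
  if (any(v[, 1] < 0.5 - 1e-9) || any(v[, 1] > grid_shape[2] + 0.5 + 1e-9) ||
      any(v[, 2] < 0.5 - 1e-9) || any(v[, 2] > grid_shape[3] + 0.5 + 1e-9))
    stop("out-of-bounds vertices")
  mask <- array(FALSE, dim = grid_shape)
  rows <- max(1L, floor(min(v[, 1]))):min(grid_shape[2], ceiling(max(v[, 1])))
  cols <- max(1L, floor(min(v[, 2]))):min(grid_shape[3], ceiling(max(v[, 2])))
  if (length(rows) && length(cols)) {
    pts <- expand.grid(row = rows, col = cols)
    inside <- .point_in_polygon(pts$row, pts$col, v)
    if (any(inside))
      mask[cbind(s, pts$row[inside], pts$col[inside])] <- TRUE
  }
  binary_mask(mask, provenance = sprintf("rasterize_contour slice %d", s))
}

# ---- circular ROIs ---------------------------------------------------------

#' Circular reference region of interest
#'
#' A physical disc on one slice, e.g. a 5-10 mm paravertebral muscle
#' reference region. The diameter is checked against `diameter_limits`
#' (default 5-10 mm, configurable).
#'
#' @param slice_index 1-based slice index.
#' @param center length-2 numeric (row, col) pixel coordinates.
#' @param diameter_mm physical diameter in mm.
#' @param diameter_limits allowed closed range for `diameter_mm`.
#' @export
circular_roi <- function(slice_index, center, diameter_mm,
                         diameter_limits = c(5, 10)) {
  if (length(center) != 2L || !all(is.finite(center)))
    stop("'center' must be finite (row, col)")
  if (diameter_mm <= 0) stop("'diameter_mm' must be > 0")
  if (diameter_mm < diameter_limits[1] || diameter_mm > diameter_limits[2])
    stop(sprintf("diameter %.3g mm outside allowed range [%g, %g]",
                 diameter_mm, diameter_limits[1], diameter_limits[2]))
  structure(list(slice_index = as.integer(slice_index),
                 center = as.numeric(center),
                 diameter_mm = as.numeric(diameter_mm)),
            class = "circular_roi")
}

#' @export
print.circular_roi <- function(x, ...) {
  cat(sprintf("<circular_roi> slice %d, center (%.2f, %.2f), diameter %.2g mm\n",
              x$slice_index, x$center[1], x$center[2], x$diameter_mm))
  invisible(x)
}

#' Extract the pixel values of a circular ROI
#'
#' Returns the values of all pixels on the ROI's slice whose centers lie
#' within `diameter_mm / 2` (physical distance, using the grid's in-plane
#' spacing) of the ROI center. Errors if the disc extends beyond the image
#' footprint.
#'
#' @param roi a [circular_roi].
#' @param grid a [voxel_grid].
#' @return Numeric vector of pixel values.
#' @export
roi_pixels <- function(roi, grid) {
  stopifnot(inherits(roi, "circular_roi"), inherits(grid, "voxel_grid"))
  d <- dim(grid$values)
  if (roi$slice_index < 1L || roi$slice_index > d[1])
    stop("ROI slice index out of bounds")
  sp <- grid$pixel_spacing_mm
  rad <- roi$diameter_mm / 2
  rad_px <- rad / sp            # (row, col) radius in pixel units
  if (roi$center[1] - rad_px[1] < 0.5 || roi$center[1] + rad_px[1] > d[2] + 0.5 ||
      roi$center[2] - rad_px[2] < 0.5 || roi$center[2] + rad_px[2] > d[3] + 0.5)
    stop("ROI extends beyond image")
  rows <- max(1L, floor(roi$center[1] - rad_px[1])):min(d[2], ceiling(roi$center[1] + rad_px[1]))
  cols <- max(1L, floor(roi$center[2] - rad_px[2])):min(d[3], ceiling(roi$center[2] + rad_px[2]))
  pts <- expand.grid(row = rows, col = cols)
  dist2 <- ((pts$row - roi$center[1]) * sp[1])^2 +
           ((pts$col - roi$center[2]) * sp[2])^2
  sel <- dist2 <= rad^2 + 1e-12
  grid$values[cbind(roi$slice_index, pts$row[sel], pts$col[sel])]
}

# Pixel indices (row, col matrix) covered by an ROI; shared with mask checks.
.roi_pixel_index <- function(roi, grid) {
  d <- dim(grid$values)
  sp <- grid$pixel_spacing_mm
  rad <- roi$diameter_mm / 2
  rad_px <- rad / sp
  rows <- max(1L, floor(roi$center[1] - rad_px[1])):min(d[2], ceiling(roi$center[1] + rad_px[1]))
  cols <- max(1L, floor(roi$center[2] - rad_px[2])):min(d[3], ceiling(roi$center[2] + rad_px[2]))
  pts <- expand.grid(row = rows, col = cols)
  dist2 <- ((pts$row - roi$center[1]) * sp[1])^2 +
           ((pts$col - roi$center[2]) * sp[2])^2
  sel <- dist2 <= rad^2 + 1e-12
  cbind(slice = roi$slice_index, row = pts$row[sel], col = pts$col[sel])
}

# ---- NIfTI I/O -------------------------------------------------------------

.sidecar_path <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path))
    sub("\\.nii(\\.gz)?$", ".json", path)
  else paste0(path, ".json")
}

#' Write a voxel grid to NIfTI-1
#'
#' The NIfTI zooms store (effective slice spacing, row spacing, col spacing);
#' the effective slice spacing is thickness + gap. Modality, thickness and
#' gap are written to a JSON sidecar next to the image so that a round trip
#' restores the grid exactly.
#'
#' @param grid a [voxel_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!dir.exists(dirname(path))) stop("unwritable path: ", dirname(path))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- c(slice_spacing(grid), grid$pixel_spacing_mm)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(modality = grid$modality,
         slice_thickness_mm = grid$slice_thickness_mm,
         slice_gap_mm = grid$slice_gap_mm),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voxel grid from NIfTI-1
#'
#' Spacings come from the header zooms (slice, row, col). Modality,
#' thickness and gap are taken from the JSON sidecar written by
#' [write_volume()] when present; otherwise `modality` must be supplied and
#' the slice zoom is interpreted as thickness with zero gap.
#'
#' @param path NIfTI file path.
#' @param modality fallback modality when no sidecar exists.
#' @export
read_volume <- function(path, modality = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("non-3-D image")
  zooms <- RNifti::pixdim(img)[1:3]
  if (any(zooms <= 0)) stop("non-positive zooms")
  side <- .sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    modality <- meta$modality
    thickness <- meta$slice_thickness_mm
    gap <- meta$slice_gap_mm
    if (abs(thickness + gap - zooms[1]) > 1e-6)
      warning("sidecar thickness+gap disagrees with slice zoom; using sidecar")
  } else {
    if (is.null(modality)) stop("no sidecar metadata; supply 'modality'")
    thickness <- zooms[1]
    gap <- 0
  }
  vals <- array(as.numeric(img), dim = d)
  voxel_grid(vals, pixel_spacing_mm = zooms[2:3],
             slice_thickness_mm = thickness, slice_gap_mm = gap,
             modality = modality)
}

# ---- contour / ROI JSON interchange ---------------------------------------
# Files store 0-based slice indices and 0-based pixel-center coordinates:
#   contour: {"slice": int, "vertices": [[r, c], ...]}
#   ROI:     {"slice": int, "center": [r, c], "diameter_mm": x}

#' Read / write contour lists (JSON interchange, 0-based coordinates)
#' @param contours list of [planar_contour].
#' @param path JSON file path.
#' @rdname contour_json
#' @export
write_contours <- function(contours, path) {
  out <- lapply(contours, function(ct) {
    list(slice = ct$slice_index - 1L,
         vertices = unname(ct$vertices - 1))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname contour_json
#' @export
read_contours <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(raw, function(ct) {
    v <- ct$vertices
    if (is.list(v)) v <- do.call(rbind, v)
    planar_contour(as.integer(ct$slice) + 1L, as.matrix(v) + 1)
  })
}

#' Read / write ROI lists (JSON interchange, 0-based coordinates)
#' @param rois list of [circular_roi].
#' @param path JSON file path.
#' @param diameter_limits passed through to [circular_roi()].
#' @rdname roi_json
#' @export
write_rois <- function(rois, path) {
  out <- lapply(rois, function(r) {
    list(slice = r$slice_index - 1L,
         center = r$center - 1,
         diameter_mm = r$diameter_mm)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname roi_json
#' @export
read_rois <- function(path, diameter_limits = c(5, 10)) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(raw, function(r) {
    circular_roi(as.integer(r$slice) + 1L, unlist(r$center) + 1,
                 r$diameter_mm, diameter_limits = diameter_limits)
  })
}
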