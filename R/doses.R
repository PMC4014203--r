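#' Create a 3D dose grid
#'
#' A `dose_grid` is the package's canonical container for a volumetric absorbed
#' dose distribution: a 3D numeric array of dose in cGy together with its
#' physical geometry. The axis convention is fixed: the first array dimension
#' runs along x (patient left-right), the second along y (anterior-posterior)
#' and the third along z (superior-inferior). `origin` is the position of the
#' *center* of voxel `[1, 1, 1]` in mm, and indices are interpreted on a
#' voxel-center basis throughout the package (a right-handed mm frame matching
#' the DICOM patient coordinate system for data read from RT Dose files).
#'
#' @param values 3D numeric array of absorbed dose (cGy). All values must be
#'   finite and non-negative.
#' @param spacing numeric length-3, voxel size in mm along (x, y, z). All > 0.
#' @param origin numeric length-3, mm position of the first voxel center.
#' @param frame free-text label of the coordinate frame (e.g. `"phantom"`,
#'   or the DICOM Frame of Reference UID for clinical data).
#' @return An object of class `dose_grid` with fields `values`, `spacing`,
#'   `origin`, `frame`.
#' @examples
#' g <- dose_grid(array(100, c(4, 4, 4)), spacing = c(3, 3, 3))
#' voxel_volume_cc(g)
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0), frame = "phantom") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  storage.mode(values) <- "double"
  spacing <- as.double(spacing)
  origin <- as.double(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  if (any(!is.finite(values)))
    stop("dose values must be finite")
  if (any(values < 0))
    stop("dose values must be non-negative (cGy)")
  structure(
    list(values = values, spacing = spacing, origin = origin,
         frame = as.character(frame)[1]),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  dose range [%.2f, %.2f] cGy, frame \"%s\"\n",
              min(x$values), max(x$values), x$frame))
  invisible(x)
}

#' Voxel-center coordinate axes of a dose grid
#'
#' @param grid a [dose_grid()].
#' @return list with numeric vectors `x`, `y`, `z` (mm, voxel centers).
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3])
}

#' Volume of one voxel in cubic centimetres
#' @param grid a [dose_grid()].
#' @export
voxel_volume_cc <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  prod(grid$spacing) / 1000
}

#' Create a 2D planar dose
#'
#' Container for a measured or extracted planar dose: a 2D matrix of dose
#' values (cGy) on a regular lattice. For ion-chamber-array measurements the
#' `active` mask marks physical detector positions (a MatriXX-like array has
#' 1020 active chambers on a 32 x 32 lattice, the four corner elements being
#' absent); for planes extracted from a 3D grid every element is active.
#' The first matrix dimension runs along the in-plane direction lying in the
#' gantry rotation plane (the "row" direction of the array — offsets along it
#' change the beam incidence angle on a detector), the second along the
#' rotation axis.
#'
#' @param values 2D numeric matrix of dose (cGy); must be finite wherever
#'   `active` is `TRUE`.
#' @param pitch numeric length-2 (or scalar), element spacing in mm.
#' @param origin numeric length-2, mm position of the first element center.
#' @param active logical matrix of the same shape; default all `TRUE`.
#' @param gantry_angle gantry angle in degrees `[0, 360)` at which the plane
#'   was acquired; `NA` when not applicable.
#' @return An object of class `planar_dose`.
#' @export
planar_dose <- function(values, pitch, origin = c(0, 0), active = NULL,
                        gantry_angle = NA_real_) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "double"
  pitch <- as.double(pitch)
  if (length(pitch) == 1L) pitch <- rep(pitch, 2L)
  if (length(pitch) != 2L || any(!is.finite(pitch)) || any(pitch <= 0))
    stop("`pitch` must be positive (mm)")
  origin <- as.double(origin)
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("`origin` must be two finite values (mm)")
  if (is.null(active)) active <- array(TRUE, dim(values))
  if (!identical(dim(active), dim(values)))
    stop("`active` mask must match the shape of `values`")
  if (any(!is.finite(values[active])))
    stop("dose values must be finite at active elements")
  if (!is.na(gantry_angle)) gantry_angle <- as.double(gantry_angle) %% 360
  structure(
    list(values = values, pitch = pitch, origin = origin,
         active = active, gantry_angle = gantry_angle),
    class = "planar_dose"
  )
}

#' @export
print.planar_dose <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<planar_dose> %d x %d elements (%d active), pitch %s mm",
              d[1], d[2], sum(x$active),
              paste(format(x$pitch), collapse = " x ")))
  if (!is.na(x$gantry_angle)) cat(sprintf(", gantry %.1f deg", x$gantry_angle))
  cat("\n")
  invisible(x)
}

#' Create a structure set
#'
#' Named binary voxel masks sharing the geometry of a [dose_grid()]:
#' planning target volumes (PTVs) and organs at risk (OARs) are represented
#' as whole-voxel membership masks. Structure volumes in cc are derived from
#' the voxel count and voxel volume.
#'
#' @param masks named list of 3D logical arrays, one per structure, each with
#'   the same dimensions as `grid$values`.
#' @param grid the [dose_grid()] defining the geometry.
#' @return An object of class `structure_set` with fields `masks`, `grid`
#'   (geometry only: values dropped), and `volumes` (named cc vector).
#' @export
structure_set <- function(masks, grid) {
  stopifnot(inherits(grid, "dose_grid"))
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stop("`masks` must be a named list of logical arrays")
  d <- dim(grid$values)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), d))
      stop(sprintf("mask \"%s\" must be a logical array matching the grid", nm))
  }
  vv <- prod(grid$spacing) / 1000
  volumes <- vapply(masks, function(m) sum(m) * vv, numeric(1))
  empty <- names(volumes)[volumes == 0]
  if (length(empty))
    warning("empty structure(s): ", paste(empty, collapse = ", "))
  structure(
    list(masks = masks, spacing = grid$spacing, origin = grid$origin,
         dim = d, frame = grid$frame, volumes = volumes),
    class = "structure_set"
  )
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures on a %s grid\n",
              length(x$masks), paste(x$dim, collapse = " x ")))
  for (nm in names(x$masks))
    cat(sprintf("  %-14s %8.2f cc\n", nm, x$volumes[[nm]]))
  invisible(x)
}

#' Create a prescription
#'
#' Prescribed dose levels per target structure plus the normalization dose
#' (the dose defining "100%" for volume metrics such as V100% and for gamma
#' criteria in prescription-normalization mode). Simultaneous-integrated-boost
#' plans carry one level per PTV.
#'
#' @param doses named numeric vector, prescribed dose in cGy per target name.
#' @param normalization dose (cGy) defining 100%; defaults to the highest
#'   prescribed level.
#' @return An object of class `prescription`.
#' @export
prescription <- function(doses, normalization = max(doses)) {
  doses <- unlist(doses)
  if (is.null(names(doses)) || any(names(doses) == ""))
    stop("`doses` must be named by target structure")
  if (any(!is.finite(doses)) || any(doses <= 0))
    stop("prescribed doses must be positive (cGy)")
  normalization <- as.double(normalization)
  if (!is.finite(normalization) || normalization <= 0)
    stop("`normalization` must be positive (cGy)")
  structure(list(doses = doses, normalization = normalization),
            class = "prescription")
}

# --- shared interpolation helpers (voxel-center convention) ----------------

# Trilinear interpolation of a dose_grid at arbitrary mm points.
# pts: N x 3 matrix. Points outside the voxel-center extent (with `tol` mm
# slack for floating-point edges) get `outside` and inside = FALSE.
interp_trilinear <- function(grid, pts, outside = 0, tol = 1e-9) {
  v <- grid$values; d <- dim(v); sp <- grid$spacing; o <- grid$origin
  fx <- (pts[, 1] - o[1]) / sp[1]
  fy <- (pts[, 2] - o[2]) / sp[2]
  fz <- (pts[, 3] - o[3]) / sp[3]
  tf <- tol / sp
  inside <- fx >= -tf[1] & fx <= d[1] - 1 + tf[1] &
            fy >= -tf[2] & fy <= d[2] - 1 + tf[2] &
            fz >= -tf[3] & fz <= d[3] - 1 + tf[3]
  fx <- pmin(pmax(fx, 0), d[1] - 1)
  fy <- pmin(pmax(fy, 0), d[2] - 1)
  fz <- pmin(pmax(fz, 0), d[3] - 1)
  i0 <- pmin(floor(fx), d[1] - 2); i0[d[1] == 1] <- 0
  j0 <- pmin(floor(fy), d[2] - 2); j0[d[2] == 1] <- 0
  k0 <- pmin(floor(fz), d[3] - 2); k0[d[3] == 1] <- 0
  i0 <- pmax(i0, 0); j0 <- pmax(j0, 0); k0 <- pmax(k0, 0)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  ix <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  i1 <- pmin(i0 + 1, d[1] - 1); j1 <- pmin(j0 + 1, d[2] - 1)
  k1 <- pmin(k0 + 1, d[3] - 1)
  val <-
    v[ix(i0, j0, k0)] * (1 - tx) * (1 - ty) * (1 - tz) +
    v[ix(i1, j0, k0)] * tx       * (1 - ty) * (1 - tz) +
    v[ix(i0, j1, k0)] * (1 - tx) * ty       * (1 - tz) +
    v[ix(i1, j1, k0)] * tx       * ty       * (1 - tz) +
    v[ix(i0, j0, k1)] * (1 - tx) * (1 - ty) * tz +
    v[ix(i1, j0, k1)] * tx       * (1 - ty) * tz +
    v[ix(i0, j1, k1)] * (1 - tx) * ty       * tz +
    v[ix(i1, j1, k1)] * tx       * ty       * tz
  val[!inside] <- outside
  list(values = val, inside = inside)
}

# Bilinear interpolation of a planar_dose (or any list with values/pitch/
# origin) at arbitrary mm points. pts: N x 2 matrix.
interp_bilinear <- function(plane, pts, outside = 0, tol = 1e-9) {
  v <- plane$values; d <- dim(v); sp <- plane$pitch; o <- plane$origin
  fx <- (pts[, 1] - o[1]) / sp[1]
  fy <- (pts[, 2] - o[2]) / sp[2]
  tf <- tol / sp
  inside <- fx >= -tf[1] & fx <= d[1] - 1 + tf[1] &
            fy >= -tf[2] & fy <= d[2] - 1 + tf[2]
  fx <- pmin(pmax(fx, 0), d[1] - 1)
  fy <- pmin(pmax(fy, 0), d[2] - 1)
  i0 <- pmax(pmin(floor(fx), d[1] - 2), 0)
  j0 <- pmax(pmin(floor(fy), d[2] - 2), 0)
  tx <- fx - i0; ty <- fy - j0
  i1 <- pmin(i0 + 1, d[1] - 1); j1 <- pmin(j0 + 1, d[2] - 1)
  ix <- function(i, j) 1 + i + d[1] * j
  val <- v[ix(i0, j0)] * (1 - tx) * (1 - ty) +
         v[ix(i1, j0)] * tx       * (1 - ty) +
         v[ix(i0, j1)] * (1 - tx) * ty +
         v[ix(i1, j1)] * tx       * ty
  val[!inside] <- outside
  list(values = val, inside = inside)
}
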