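#' Rasterize contour stacks onto a dose grid
#'
#' Converts per-slice closed polygons (the representation used by DICOM RT
#' Structure Sets) into whole-voxel membership masks on a [dose_grid()]
#' geometry. A voxel belongs to a structure iff its *center* lies inside the
#' slice polygon under the even-odd rule; no partial-volume weighting is
#' applied. Several polygons on one slice combine by even-odd parity, so
#' disjoint polygons union and nested polygons produce holes.
#'
#' @param contours named list (one entry per structure). Each structure is a
#'   list of slices; each slice is a list with `z` (slice position, mm) and
#'   `xy` (an N x 2 matrix of in-plane vertex coordinates in mm, closed:
#'   first vertex repeated as the last).
#' @param grid the target [dose_grid()] geometry.
#' @return A [structure_set()] on `grid`. Structures whose contours all fall
#'   outside the grid get empty masks (with a warning).
#' @details Slices are assigned to the nearest voxel layer in z; a slice
#'   whose position lies outside the grid extent (beyond half a voxel from
#'   the outermost layer) is ignored with a warning. A polygon whose first
#'   and last vertices differ is rejected, naming the structure.
#' @export
rasterize_contours <- function(contours, grid) {
  stopifnot(inherits(grid, "dose_grid"))
  ax <- grid_axes(grid)
  d <- dim(grid$values)
  masks <- list()
  for (nm in names(contours)) {
    mask <- array(FALSE, d)
    for (slice in contours[[nm]]) {
      poly <- slice$xy
      if (!is.matrix(poly) || ncol(poly) != 2L || nrow(poly) < 4L)
        stop(sprintf("structure \"%s\": polygon must be an N x 2 matrix with N >= 4", nm))
      if (max(abs(poly[1, ] - poly[nrow(poly), ])) > 1e-6)
        stop(sprintf("structure \"%s\": polygon is not closed", nm))
      # nearest layer, ties upward (round-half-even would fold adjacent
      # half-offset slices onto one layer, where the parity XOR cancels)
      k <- floor((slice$z - grid$origin[3]) / grid$spacing[3] + 0.5) + 1
      if (k < 1 || k > d[3] ||
          abs(slice$z - ax$z[k]) > grid$spacing[3] / 2 + 1e-9) {
        warning(sprintf("structure \"%s\": slice at z = %g mm outside grid, ignored",
                        nm, slice$z))
        next
      }
      inside <- polygon_parity(ax$x, ax$y, poly)
      mask[, , k] <- xor(mask[, , k], inside)
    }
    masks[[nm]] <- mask
  }
  structure_set(masks, grid)
}

# Even-odd (crossing-number parity) test of all (x_i, y_j) lattice points
# against one closed polygon. Returns a logical length(x) x length(y) matrix.
# Half-open edge rule [y0, y1) makes shared vertices count once.
polygon_parity <- function(x, y, poly) {
  n <- nrow(poly) - 1L # last vertex repeats the first
  res <- matrix(FALSE, length(x), length(y))
  # restrict to the polygon's bounding box for speed
  xi <- which(x >= min(poly[, 1]) - 1e-12 & x <= max(poly[, 1]) + 1e-12)
  yi <- which(y >= min(poly[, 2]) - 1e-12 & y <= max(poly[, 2]) + 1e-12)
  if (!length(xi) || !length(yi)) return(res)
  px <- x[xi]
  for (j in yi) {
    yy <- y[j]
    crossings <- rep(0L, length(px))
    for (e in seq_len(n)) {
      y0 <- poly[e, 2]; y1 <- poly[e + 1, 2]
      if ((y0 <= yy) == (y1 <= yy)) next # edge does not straddle the ray
      xcross <- poly[e, 1] + (yy - y0) / (y1 - y0) * (poly[e + 1, 1] - poly[e, 1])
      crossings <- crossings + (px < xcross)
    }
    res[xi, j] <- crossings %% 2L == 1L
  }
  res
}

#' Resample a dose grid onto a new geometry
#'
#' Trilinear interpolation of a dose distribution onto a target voxel-center
#' lattice. Values outside the source extent are set to 0 rather than
#' extrapolated — dose beyond the measured or calculated extent is unknown —
#' and the out-of-extent voxels are recorded in an `inside` mask attached to
#' the result.
#'
#' @param dose source [dose_grid()].
#' @param target a [dose_grid()] (values ignored) or a list with `dim`,
#'   `spacing`, `origin` describing the output geometry.
#' @return A [dose_grid()] on the target geometry, with attribute `inside`
#'   (logical array: `TRUE` where the target voxel center lay within the
#'   source extent).
#' @export
resample_to_grid <- function(dose, target) {
  stopifnot(inherits(dose, "dose_grid"))
  if (inherits(target, "dose_grid")) {
    tdim <- dim(target$values); tsp <- target$spacing; tor <- target$origin
    frame <- target$frame
  } else {
    tdim <- as.integer(target$dim); tsp <- as.double(target$spacing)
    tor <- as.double(target$origin)
    frame <- if (!is.null(target$frame)) target$frame else dose$frame
  }
  if (identical(tdim, dim(dose$values)) &&
      isTRUE(all.equal(tsp, dose$spacing, tolerance = 0)) &&
      isTRUE(all.equal(tor, dose$origin, tolerance = 0))) {
    out <- dose_grid(dose$values, tsp, tor, frame)
    attr(out, "inside") <- array(TRUE, tdim)
    return(out)
  }
  ax <- list(x = tor[1] + (seq_len(tdim[1]) - 1) * tsp[1],
             y = tor[2] + (seq_len(tdim[2]) - 1) * tsp[2],
             z = tor[3] + (seq_len(tdim[3]) - 1) * tsp[3])
  sax <- grid_axes(dose)
  if (max(ax$x) < min(sax$x) || min(ax$x) > max(sax$x) ||
      max(ax$y) < min(sax$y) || min(ax$y) > max(sax$y) ||
      max(ax$z) < min(sax$z) || min(ax$z) > max(sax$z))
    stop("target geometry does not overlap the source extent")
  pts <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z,
                               KEEP.OUT.ATTRS = FALSE))
  ires <- interp_trilinear(dose, pts, outside = 0)
  out <- dose_grid(array(ires$values, tdim), tsp, tor, frame)
  attr(out, "inside") <- array(ires$inside, tdim)
  out
}

#' Extract a planar dose from a 3D grid
#'
#' Interpolates the dose on the plane perpendicular to `axis` at the given
#' coordinate (linear interpolation between the two bracketing voxel layers;
#' in-plane values stay on the voxel-center lattice). Used e.g. to obtain the
#' isocenter-plane dose that a planar measurement is compared against.
#'
#' @param dose a [dose_grid()].
#' @param axis one of `"x"`, `"y"`, `"z"` — the axis perpendicular to the
#'   requested plane.
#' @param coordinate plane position along `axis`, in mm; must lie within the
#'   grid's voxel-center extent.
#' @return A [planar_dose()] whose first dimension runs along the first
#'   remaining grid axis and second along the other (x-y for `axis = "z"`,
#'   x-z for `"y"`, y-z for `"x"`), pitch and origin inherited from the
#'   in-plane grid spacings.
#' @export
extract_plane <- function(dose, axis = c("z", "y", "x"), coordinate) {
  stopifnot(inherits(dose, "dose_grid"))
  axis <- match.arg(axis)
  k <- match(axis, c("x", "y", "z"))
  ax <- grid_axes(dose)[[k]]
  if (coordinate < min(ax) - 1e-9 || coordinate > max(ax) + 1e-9)
    stop(sprintf("coordinate %g mm outside grid extent along %s", coordinate, axis))
  f <- (coordinate - dose$origin[k]) / dose$spacing[k]
  f <- min(max(f, 0), length(ax) - 1)
  i0 <- min(floor(f), length(ax) - 2); i0 <- max(i0, 0)
  t <- f - i0
  sl <- function(i) {
    switch(axis,
           x = dose$values[i + 1, , ],
           y = dose$values[, i + 1, ],
           z = dose$values[, , i + 1])
  }
  vals <- if (length(ax) == 1L) sl(0) else (1 - t) * sl(i0) + t * sl(i0 + 1)
  keep <- setdiff(1:3, k)
  planar_dose(as.matrix(vals),
              pitch = dose$spacing[keep],
              origin = dose$origin[keep])
}
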