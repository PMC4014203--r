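#' Incident angle of an off-axis detector
#'
#' For a detector offset d (mm, signed, along the array row direction lying
#' in the gantry rotation plane) from the array center, a gantry angle theta
#' and a source-axis distance SAD, the beam incidence angle on the detector
#' is the quadrant-correct arctangent
#' phi = atan2(d + SAD sin(theta), SAD cos(theta)), mapped to [0, 360).
#' A central detector (d = 0) sees phi = theta for every theta; the
#' two-argument arctangent keeps the formula defined at theta = 90 and 270
#' degrees and in the posterior half where cos(theta) < 0.
#'
#' @param d signed in-plane offset from the array center, mm (vectorised).
#' @param theta gantry angle, degrees.
#' @param SAD source-axis distance, mm (> 0); 1000 mm for a standard linac.
#' @return Incident angle(s) phi in degrees, `[0, 360)`.
#' @export
incident_angle <- function(d, theta, SAD = 1000) {
  if (!is.finite(SAD) || SAD <= 0) stop("SAD must be positive (mm)")
  th <- theta * pi / 180
  phi <- atan2(d + SAD * sin(th), SAD * cos(th)) * 180 / pi
  phi %% 360
}

#' Gantry-angle sampling grid for response-correction measurements
#'
#' Angles 0 to 360 degrees in 5-degree steps, refined to 1-degree steps
#' within 90 +/- 5 and 270 +/- 5 degrees where the chamber response varies
#' fastest (beam incidence near-parallel to the detector plane).
#'
#' @return Sorted numeric vector of angles in `[0, 360)`.
#' @export
angle_sampling_grid <- function() {
  sort(unique(c(seq(0, 355, by = 5), 85:95, 265:275)))
}

#' Construct a correction table
#'
#' Validates and wraps a set of (gantry angle, correction factor) samples.
#' The factor at 0 degrees must be exactly 1 (factors are normalized to the
#' zero-degree response); all factors must be positive and angles strictly
#' increasing in `[0, 360)`. Interpolation between samples is periodic across
#' the 360 -> 0 wrap.
#'
#' @param angles sample angles, degrees in `[0, 360)`, strictly increasing,
#'   containing 0.
#' @param factors response correction factors (> 0), `factors[angles == 0]`
#'   equal to 1.
#' @param SAD source-axis distance the table applies to, mm.
#' @param meta named list of free-form metadata (date, beam quality, ...).
#' @return Object of class `correction_table`.
#' @export
correction_table <- function(angles, factors, SAD = 1000, meta = list()) {
  angles <- as.double(angles); factors <- as.double(factors)
  if (length(angles) != length(factors) || length(angles) < 2)
    stop("angles and factors must be equal-length (>= 2)")
  if (is.unsorted(angles, strictly = TRUE))
    stop("angles must be strictly increasing")
  if (any(angles < 0) || any(angles >= 360))
    stop("angles must lie in [0, 360)")
  if (angles[1] != 0) stop("table must contain a 0-degree sample")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("factors must be positive")
  if (abs(factors[1] - 1) > 1e-12)
    stop("factor at 0 degrees must equal 1 (normalization)")
  structure(list(angles = angles, factors = factors, SAD = SAD, meta = meta),
            class = "correction_table")
}

#' @export
print.correction_table <- function(x, ...) {
  cat(sprintf("<correction_table> %d samples, factors [%.4f, %.4f], SAD %g mm\n",
              length(x$angles), min(x$factors), max(x$factors), x$SAD))
  invisible(x)
}

#' Build a correction table from paired central-detector series
#'
#' At each sampled gantry angle the central detector's dose is measured and
#' the same point dose is calculated by the planning system. The angular
#' response correction factor is the calculated/measured ratio normalized to
#' its value at zero degrees:
#' factor(theta) = (calc(theta)/meas(theta)) / (calc(0)/meas(0)).
#' A detector whose response drops at some angle (measures low) thus gets a
#' factor > 1 there. The factors apply to all chambers of the array, looked
#' up at each chamber's own incident angle.
#'
#' @param angles sampled gantry angles, degrees (must include 0; any order).
#' @param measured central-detector measured doses (cGy), > 0.
#' @param calculated planning-system doses at the same point (cGy), > 0.
#' @param SAD source-axis distance, mm.
#' @param meta named list of metadata.
#' @return A [correction_table()].
#' @export
build_correction_table <- function(angles, measured, calculated, SAD = 1000,
                                   meta = list()) {
  angles <- as.double(angles) %% 360
  if (length(measured) != length(angles) || length(calculated) != length(angles))
    stop("angles, measured and calculated must have equal length")
  if (any(!is.finite(measured)) || any(measured <= 0) ||
      any(!is.finite(calculated)) || any(calculated <= 0))
    stop("doses must be positive")
  i0 <- which(angles == 0)
  if (length(i0) != 1) stop("series must contain exactly one 0-degree entry")
  ratio <- calculated / measured
  fac <- ratio / ratio[i0]
  ord <- order(angles)
  correction_table(angles[ord], fac[ord], SAD = SAD, meta = meta)
}

#' Interpolate a correction factor at an arbitrary incident angle
#'
#' Linear interpolation between the bracketing sampled angles, periodic
#' across the 360 -> 0 degree wrap (the 0-degree sample also serves as the
#' 360-degree sample).
#'
#' @param table a [correction_table()].
#' @param phi incident angle(s), degrees (any real; reduced mod 360).
#' @return Interpolated factor(s).
#' @export
correction_factor_at <- function(table, phi) {
  stopifnot(inherits(table, "correction_table"))
  phi <- as.double(phi) %% 360
  stats::approx(c(table$angles, 360), c(table$factors, table$factors[1]),
                xout = phi, method = "linear")$y
}

#' Apply angular response correction to a planar measurement
#'
#' Multiplies each active detector's reading by the correction factor at its
#' own incident angle: phi_i = [incident_angle()] of the detector's signed
#' row offset d_i at the frame's recorded gantry angle. Detectors sharing a
#' row offset (same first-axis position) share a factor; offsets along the
#' rotation axis do not change the incidence and need none. The array center
#' is the midpoint of the detector lattice.
#'
#' Composite (multi-gantry-angle) measurements are corrected per delivered
#' frame at its recorded angle and then summed; correction is linear, so the
#' order of correction and summation does not matter within one frame set.
#'
#' @param measurement a [planar_dose()] carrying its `gantry_angle`.
#' @param table a [correction_table()].
#' @param SAD source-axis distance, mm; defaults to the table's.
#' @return The corrected [planar_dose()].
#' @export
apply_correction <- function(measurement, table, SAD = table$SAD) {
  stopifnot(inherits(measurement, "planar_dose"),
            inherits(table, "correction_table"))
  if (is.na(measurement$gantry_angle))
    stop("measurement carries no gantry angle")
  d <- detector_offsets(measurement)
  phi <- incident_angle(d, measurement$gantry_angle, SAD)
  fac <- correction_factor_at(table, phi)
  out <- measurement
  out$values <- measurement$values * fac # recycles down columns (rows share d)
  out$values[!out$active] <- measurement$values[!out$active]
  out
}

# Signed offsets (mm) of each first-axis lattice position from the array
# center (midpoint of the lattice extent).
detector_offsets <- function(plane) {
  n <- nrow(plane$values)
  x <- plane$origin[1] + (seq_len(n) - 1) * plane$pitch[1]
  x - (plane$origin[1] + (n - 1) * plane$pitch[1] / 2)
}

#' Sum a list of planar frames
#'
#' Element-wise sum of per-beam planar doses into a composite; all frames
#' must share geometry and active mask. The composite's gantry angle is `NA`.
#'
#' @param frames list of [planar_dose()] objects.
#' @return A [planar_dose()].
#' @export
sum_planar <- function(frames) {
  stopifnot(length(frames) >= 1)
  base <- frames[[1]]
  acc <- base$values
  for (f in frames[-1]) {
    if (!identical(dim(f$values), dim(base$values)) ||
        !isTRUE(all.equal(f$pitch, base$pitch)) ||
        !isTRUE(all.equal(f$origin, base$origin)))
      stop("frames must share geometry")
    acc <- acc + f$values
  }
  planar_dose(acc, base$pitch, base$origin, base$active)
}
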