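#' Empty phantom dose grid
#'
#' Geometry of a rectangular solid-water phantom (default exterior
#' 31.4 cm x 34 cm x 22 cm, matching a MULTICube-like insert phantom),
#' voxelised at the given spacing (default 3 mm, a typical planning grid) and
#' centered on the origin. Voxel counts are the ceiling of extent/spacing so
#' the grid always covers the stated box.
#'
#' @param spacing voxel size, mm (scalar or length 3; > 0).
#' @param dims_cm phantom exterior dimensions in cm along (x, y, z).
#' @return A [dose_grid()] of zeros.
#' @export
make_phantom <- function(spacing = 3, dims_cm = c(31.4, 34, 22)) {
  spacing <- as.double(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive (mm)")
  dims_mm <- as.double(dims_cm) * 10
  n <- as.integer(ceiling(dims_mm / spacing))
  origin <- -(n - 1) * spacing / 2
  dose_grid(array(0, n), spacing, origin, frame = "phantom")
}

#' Synthetic nasopharyngeal-carcinoma-like structure set
#'
#' Deterministic anatomical template on a phantom grid emulating a
#' head-and-neck plan: three nested targets — PTVnx (primary nasopharynx
#' tumour, an ellipsoid), PTV1 (high-risk subclinical region, the same
#' ellipsoid expanded by `margin1`) and PTV2 (preventive irradiation region,
#' expanded by a further `margin2`) — plus serial organs at risk (brainstem
#' and spinal cord as posterior cylinders, thin optic nerves and the chiasm)
#' and parallel organs (lateral parotid glands). Concentric expansion makes
#' the nesting PTVnx subset of PTV1 subset of PTV2 hold voxelwise by
#' construction. An optional seeded jitter displaces structure centers to
#' create per-case anatomical variation; the same seed always reproduces the
#' same masks.
#'
#' @param grid a [dose_grid()] geometry (the default 3 mm phantom fits).
#' @param seed integer seed for the jitter; `NULL` disables jitter.
#' @param jitter standard deviation (mm) of the center displacement.
#' @param margin1,margin2 isotropic expansion margins (mm) producing PTV1
#'   from PTVnx and PTV2 from PTV1.
#' @return A [structure_set()].
#' @export
make_npc_structures <- function(grid, seed = NULL, jitter = 0,
                                margin1 = 7, margin2 = 10) {
  stopifnot(inherits(grid, "dose_grid"))
  ax <- grid_axes(grid)
  need <- rbind(c(-70, 70), c(-35, 65), c(-105, 85)) # template bounding box, mm
  ext <- rbind(range(ax$x), range(ax$y), range(ax$z))
  if (any(need[, 1] < ext[, 1] - 1e-9) || any(need[, 2] > ext[, 2] + 1e-9))
    stop("grid too small for the NPC template")

  jit <- function() c(0, 0, 0)
  if (!is.null(seed) && jitter > 0) {
    rng <- local_rng(seed)
    on.exit(rng(), add = TRUE)
    jit <- function() stats::rnorm(3, 0, jitter)
  }

  d <- dim(grid$values)
  X <- array(ax$x, d)
  Y <- array(rep(ax$y, each = d[1]), d)
  Z <- array(rep(ax$z, each = d[1] * d[2]), d)

  ellipsoid <- function(center, semi) {
    ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
      ((Z - center[3]) / semi[3])^2 <= 1
  }
  zcylinder <- function(center_xy, radius, zrange) {
    (X - center_xy[1])^2 + (Y - center_xy[2])^2 <= radius^2 &
      Z >= zrange[1] & Z <= zrange[2]
  }
  segment_tube <- function(p0, p1, radius) {
    v <- p1 - p0
    L2 <- sum(v^2)
    t <- ((X - p0[1]) * v[1] + (Y - p0[2]) * v[2] + (Z - p0[3]) * v[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    (X - p0[1] - t * v[1])^2 + (Y - p0[2] - t * v[2])^2 +
      (Z - p0[3] - t * v[3])^2 <= radius^2
  }

  cnx <- c(0, 10, 10) + jit()
  semi_nx <- c(25, 20, 20)
  masks <- list(
    PTVnx = ellipsoid(cnx, semi_nx),
    PTV1 = ellipsoid(cnx, semi_nx + margin1),
    PTV2 = ellipsoid(cnx, semi_nx + margin1 + margin2),
    brainstem = zcylinder((c(0, 45, 0) + jit())[1:2], 10, c(10, 80)),
    spinal_cord = zcylinder((c(0, 55, 0) + jit())[1:2], 5, c(-100, 10)),
    parotid_l = ellipsoid(c(-55, 20, 5) + jit(), c(12, 15, 20)),
    parotid_r = ellipsoid(c(55, 20, 5) + jit(), c(12, 15, 20)),
    optic_nerve_l = segment_tube(c(-5, -15, 40), c(-30, -25, 40) + jit(), 2.5),
    optic_nerve_r = segment_tube(c(5, -15, 40), c(30, -25, 40) + jit(), 2.5),
    optic_chiasm = ellipsoid(c(0, -10, 40) + jit(), c(8, 6, 4))
  )
  structure_set(masks, grid)
}

# Save/restore the global RNG state around seeded generation; returns the
# restore function.
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Analytic planned dose for a synthetic plan
#'
#' Builds a conformal dose distribution as the voxelwise maximum, over the
#' prescribed targets, of the prescription level times the target indicator
#' blurred with an isotropic Gaussian of width `sigma` (the penumbra
#' falloff). Deep inside a large target the blur saturates and the dose
#' equals the prescription; across the target edge it falls off over a few
#' sigma, emulating the penumbra of a highly conformal plan without any
#' transport calculation (this package verifies dose *comparisons*, not dose
#' engines).
#'
#' @param structures a [structure_set()] containing every prescribed target.
#' @param prescription a [prescription()]; each named level must match a
#'   structure.
#' @param sigma penumbra falloff width, mm (> 0).
#' @param normalize renormalize the plan the way clinical plans are
#'   prescribed: scale the whole distribution so the boost target (highest
#'   prescription level) has D95% equal to its prescription. Off by
#'   default, where the dose is exactly the blurred-indicator maximum and
#'   saturates at the prescription deep inside a large target.
#' @return A [dose_grid()] (cGy) on the structure-set geometry.
#' @export
make_planned_dose <- function(structures, prescription, sigma = 4,
                              normalize = FALSE) {
  stopifnot(inherits(structures, "structure_set"),
            inherits(prescription, "prescription"))
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be positive (mm)")
  targets <- names(prescription$doses)
  missing <- setdiff(targets, names(structures$masks))
  if (length(missing))
    stop("no mask for prescribed target(s): ", paste(missing, collapse = ", "))
  acc <- array(0, structures$dim)
  for (t in targets) {
    ind <- blur3d(structures$masks[[t]] * 1, sigma, structures$spacing)
    acc <- pmax(acc, prescription$doses[[t]] * ind)
  }
  out <- dose_grid(acc, structures$spacing, structures$origin,
                   structures$frame)
  if (normalize) {
    boost <- targets[which.max(unlist(prescription$doses[targets]))]
    d95 <- dose_at_volume(cumulative_dvh(out, boost, structures), 0.95)
    if (d95 > 0)
      out$values <- out$values * (prescription$doses[[boost]] / d95)
  }
  out
}

# Separable zero-padded Gaussian blur of a 3D array (sigma in mm, truncated
# at 4 sigma). Shift-and-add with a fixed accumulation order, so results are
# bitwise reproducible regardless of the linear-algebra backend.
blur3d <- function(arr, sigma, spacing) {
  if (sigma == 0) return(arr)
  d <- dim(arr)
  for (a in 1:3) {
    h <- ceiling(4 * sigma / spacing[a])
    k <- stats::dnorm((-h:h) * spacing[a], sd = sigma)
    k <- k / sum(k)
    n <- d[a]
    perm <- c(a, setdiff(1:3, a))
    m <- matrix(aperm(arr, perm), n, prod(d[-a]))
    acc <- matrix(0, n, ncol(m))
    for (off in -h:h) {
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      acc[ok, ] <- acc[ok, ] + k[off + h + 1] * m[src[ok], ]
    }
    arr <- aperm(array(acc, d[perm]), order(perm))
  }
  arr
}

#' Delivery perturbation specification
#'
#' Parametrises the delivery deviations the pipeline is meant to detect:
#' a rigid spatial shift (e.g. setup or collimator-sag displacement), a
#' global output-scale factor, extra penumbra broadening, and additive
#' Gaussian noise. Identical seeds reproduce identical perturbed doses.
#'
#' @param shift rigid shift vector, mm (x, y, z).
#' @param scale global multiplicative dose factor (> 0).
#' @param blur extra isotropic Gaussian blur width, mm (>= 0), broadening
#'   the penumbra falloff.
#' @param noise additive Gaussian noise standard deviation, percent of the
#'   reference dose level (>= 0).
#' @param seed integer seed for the noise.
#' @return Object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(shift = c(0, 0, 0), scale = 1, blur = 0,
                              noise = 0, seed = 1L) {
  shift <- as.double(shift)
  if (length(shift) != 3L || any(!is.finite(shift))) stop("bad `shift`")
  if (!is.finite(scale) || scale <= 0) stop("`scale` must be > 0")
  if (!is.finite(blur) || blur < 0) stop("`blur` must be >= 0 (mm)")
  if (!is.finite(noise) || noise < 0) stop("`noise` must be >= 0 (%)")
  structure(list(shift = shift, scale = scale, blur = blur, noise = noise,
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Apply a delivery perturbation to a dose grid
#'
#' Applies, in this documented order: (1) the rigid shift — the distribution
#' moves by `shift`, i.e. the output at x is the input trilinearly sampled
#' at x - shift, 0 outside the original extent; (2) the global scale;
#' (3) the extra penumbra blur; (4) seeded additive Gaussian noise with
#' standard deviation `noise`% of `noise_ref`, truncated at zero so the
#' result remains a valid dose. The identity spec returns the input
#' unchanged, bit for bit.
#'
#' @param dose a [dose_grid()].
#' @param spec a [perturbation_spec()].
#' @param noise_ref reference dose level (cGy) the noise percentage refers
#'   to; defaults to the maximum planned dose.
#' @return The perturbed [dose_grid()].
#' @export
perturb_dose <- function(dose, spec, noise_ref = max(dose$values)) {
  stopifnot(inherits(dose, "dose_grid"), inherits(spec, "perturbation_spec"))
  v <- dose$values
  if (any(spec$shift != 0)) {
    d <- dim(v)
    ax <- grid_axes(dose)
    pts <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z,
                                 KEEP.OUT.ATTRS = FALSE))
    pts <- sweep(pts, 2, spec$shift, "-")
    v <- array(interp_trilinear(dose, pts, outside = 0)$values, d)
  }
  if (spec$scale != 1) v <- v * spec$scale
  if (spec$blur > 0) v <- blur3d(v, spec$blur, dose$spacing)
  if (spec$noise > 0) {
    rng <- local_rng(spec$seed)
    on.exit(rng(), add = TRUE)
    v <- v + stats::rnorm(length(v), 0, spec$noise / 100 * noise_ref)
    v <- pmax(v, 0)
  }
  dose_grid(v, dose$spacing, dose$origin, dose$frame)
}

#' Sample a planar field on an ion-chamber-array lattice
#'
#' Bilinearly samples a continuous planar dose at the detector positions of
#' a 2D array: an `n[1] x n[2]` lattice (default 32 x 32) with the stated
#' pitch (default 7.62 mm between chamber centers), centered at `center`.
#' The four corner lattice positions carry no physical chamber, so the
#' default layout has 1020 active elements.
#'
#' @param field a [planar_dose()] covering the array extent.
#' @param pitch detector pitch, mm.
#' @param n lattice size (length 2).
#' @param center array center in field coordinates, mm.
#' @param gantry_angle gantry angle recorded on the sampled frame; defaults
#'   to the field's.
#' @return A [planar_dose()] with the array's active mask (inactive corners
#'   read 0).
#' @export
sample_detector_array <- function(field, pitch = 7.62, n = c(32L, 32L),
                                  center = c(0, 0),
                                  gantry_angle = field$gantry_angle) {
  stopifnot(inherits(field, "planar_dose"))
  n <- as.integer(n)
  origin <- center - (n - 1) * pitch / 2
  xs <- origin[1] + (seq_len(n[1]) - 1) * pitch
  ys <- origin[2] + (seq_len(n[2]) - 1) * pitch
  pts <- as.matrix(expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE))
  ir <- interp_bilinear(field, pts)
  if (!all(ir$inside))
    stop("array extent lies outside the planar field")
  active <- matrix(TRUE, n[1], n[2])
  active[c(1, n[1]), c(1, n[2])] <- FALSE # no chambers at the 4 corners
  vals <- matrix(ir$values, n[1], n[2])
  vals[!active] <- 0
  planar_dose(vals, pitch, origin, active, gantry_angle)
}

#' Angular response model of an ion-chamber array
#'
#' Smooth synthetic relative-response curve R(phi) of a plane-parallel
#' chamber versus beam incidence angle: unity at normal incidence, with
#' Gaussian dips of amplitude `A` and width `w` (degrees, standard
#' deviation) centered at 90 and 270 degrees — where the beam runs parallel
#' to the detector plane and the response drops most — plus a gentle
#' `ripple * sin^2(phi)` modulation. The curve is normalized so R(0) = 1
#' exactly and must remain positive everywhere.
#'
#' @param A dip amplitude (0 <= A < 1).
#' @param w dip width, degrees (> 0).
#' @param ripple ripple amplitude (>= 0).
#' @return Object of class `response_model`.
#' @export
response_model <- function(A = 0.2, w = 10, ripple = 0.005) {
  if (!is.finite(A) || A < 0 || A >= 1) stop("`A` must lie in [0, 1)")
  if (!is.finite(w) || w <= 0) stop("`w` must be positive (degrees)")
  if (!is.finite(ripple) || ripple < 0) stop("`ripple` must be >= 0")
  m <- structure(list(A = A, w = w, ripple = ripple), class = "response_model")
  if (min(response_at(m, seq(0, 359.5, by = 0.5))) <= 0)
    stop("response must stay positive: reduce `A` or `ripple`")
  m
}

#' Evaluate an angular response model
#'
#' @param model a [response_model()].
#' @param phi incident angle(s), degrees.
#' @return Relative response R(phi), with R(0) = 1.
#' @export
response_at <- function(model, phi) {
  stopifnot(inherits(model, "response_model"))
  raw <- function(p) {
    dip <- function(c0) {
      dd <- abs((p - c0) %% 360)
      dd <- pmin(dd, 360 - dd)
      exp(-dd^2 / (2 * model$w^2))
    }
    1 - model$A * (dip(90) + dip(270)) -
      model$ripple * sin(p * pi / 180)^2
  }
  raw(phi) / raw(0)
}

#' Imprint an angular response on a measured frame
#'
#' Ground-truth generator for correction studies: multiplies each active
#' detector's value by R(phi_i), where phi_i is the detector's incident
#' angle ([incident_angle()]) at the frame's gantry angle. The corresponding
#' inverse operation is [apply_correction()] with a table built from a
#' central-detector angle series.
#'
#' @param frame a [planar_dose()] (true fluence) carrying its gantry angle,
#'   or with `theta` supplied.
#' @param model a [response_model()].
#' @param SAD source-axis distance, mm.
#' @param theta gantry angle override, degrees.
#' @return The frame as the array would have measured it.
#' @export
simulate_angular_response <- function(frame, model, SAD = 1000,
                                      theta = frame$gantry_angle) {
  stopifnot(inherits(frame, "planar_dose"), inherits(model, "response_model"))
  if (is.na(theta)) stop("frame carries no gantry angle")
  d <- detector_offsets(frame)
  r <- response_at(model, incident_angle(d, theta, SAD))
  out <- frame
  out$values <- frame$values * r # recycles along rows: one factor per offset
  out$values[!out$active] <- frame$values[!out$active]
  out$gantry_angle <- as.double(theta) %% 360
  out
}
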