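#' Gamma-index acceptance criteria
#'
#' Bundles the parameters of a gamma comparison: the dose tolerance as a
#' percentage of the normalization dose, the distance-to-agreement (DTA) in
#' mm, how the normalization dose is chosen, and the low-dose threshold below
#' which reference points are excluded from *global* pass-rate counting.
#' The clinical default is the (3%, 3 mm) criterion with a 20 cGy threshold.
#'
#' @param dose_tol dose tolerance, percent of the normalization dose (> 0).
#' @param dta distance to agreement, mm (> 0).
#' @param norm normalization mode: `"global_reference_max"` (percent of the
#'   maximum reference dose — the default for planar comparisons),
#'   `"prescription"` (percent of a prescription dose supplied at compute
#'   time — the usual choice for volumetric comparisons), or `"local"`
#'   (percent of the local reference dose at each point).
#' @param threshold low-dose threshold in cGy, applied to the *reference*
#'   (planned) dose when counting the global pass rate; per-structure pass
#'   rates ignore it.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tol = 3, dta = 3,
                           norm = c("global_reference_max", "prescription",
                                    "local"),
                           threshold = 20) {
  norm <- match.arg(norm)
  if (!is.finite(dose_tol) || dose_tol <= 0) stop("`dose_tol` must be > 0")
  if (!is.finite(dta) || dta <= 0) stop("`dta` must be > 0 (mm)")
  if (!is.finite(threshold) || threshold < 0) stop("`threshold` must be >= 0 (cGy)")
  structure(list(dose_tol = dose_tol, dta = dta, norm = norm,
                 threshold = threshold),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %g%% / %g mm, norm = %s, threshold = %g cGy\n",
              x$dose_tol, x$dta, x$norm, x$threshold))
  invisible(x)
}

# Resolve geometry of a dose_grid / planar_dose into the padded 3-axis form
# the search kernel expects (planar inputs get a unit third axis).
as_lattice3 <- function(x) {
  if (inherits(x, "dose_grid")) {
    list(values = as.double(x$values), dim = dim(x$values),
         spacing = x$spacing, origin = x$origin, ndim = 3L)
  } else if (inherits(x, "planar_dose")) {
    v <- x$values
    v[!x$active] <- 0 # inactive elements carry no signal
    list(values = as.double(v), dim = c(dim(v), 1L),
         spacing = c(x$pitch, 1), origin = c(x$origin, 0), ndim = 2L)
  } else stop("expected a dose_grid or planar_dose")
}

resolve_norm_dose <- function(reference, criteria, norm_dose) {
  switch(criteria$norm,
    global_reference_max = {
      mx <- if (inherits(reference, "planar_dose"))
        max(reference$values[reference$active]) else max(reference$values)
      if (mx <= 0) stop("normalization dose is zero (reference has no dose)")
      mx
    },
    prescription = {
      if (is.null(norm_dose))
        stop("criteria use prescription normalization: supply `norm_dose`")
      if (inherits(norm_dose, "prescription")) norm_dose <- norm_dose$normalization
      if (!is.finite(norm_dose) || norm_dose <= 0)
        stop("normalization dose must be positive")
      norm_dose
    },
    local = NA_real_
  )
}

#' Compute a gamma-index map
#'
#' For every reference point r the gamma index is the minimum, over evaluated
#' positions r' within the search radius, of
#' sqrt(|r' - r|^2 / dta^2 + (De(r') - Dr(r))^2 / dD^2),
#' where dD is the dose tolerance expressed in cGy. The evaluated dose is
#' continuously (bi-/trilinearly) interpolated during the search; the
#' minimisation runs over a displacement lattice of spacing `dta/subsample`
#' out to `radius_factor * dta`, scanned in order of increasing distance with
#' an exact early exit (the result equals a full scan of that lattice; the
#' residual difference from the continuum minimum is bounded by
#' [gamma_lattice_bound()]).
#'
#' Gamma is computed at every reference point (every active element for
#' planar input); the result's `evaluated` mask additionally applies the
#' low-dose threshold and is what the *global* pass rate counts.
#'
#' @param reference planned dose: a [dose_grid()] or [planar_dose()].
#' @param evaluated measured/reconstructed dose of the same dimensionality.
#' @param criteria a [gamma_criteria()].
#' @param norm_dose normalization dose in cGy (or a [prescription()]);
#'   required when `criteria$norm == "prescription"`, ignored otherwise.
#' @param subsample displacement-lattice refinement: the search step is
#'   `dta/subsample` mm (default 10).
#' @param radius_factor search radius as a multiple of `dta` (default 3).
#' @param compute_mask optional logical array (reference shape): restrict the
#'   gamma computation to these points (e.g. one structure, for speed).
#' @return An object of class `gamma_result`: `gamma` (array aligned to the
#'   reference geometry; `NA` where not computed), `evaluated` (logical array
#'   used for global counting), `criteria`, `norm_dose`, `subsample`,
#'   `radius`, and the reference geometry.
#' @export
compute_gamma <- function(reference, evaluated, criteria = gamma_criteria(),
                          norm_dose = NULL, subsample = 10, radius_factor = 3,
                          compute_mask = NULL) {
  if (inherits(reference, "dose_grid") != inherits(evaluated, "dose_grid"))
    stop("reference and evaluated must have the same dimensionality")
  stopifnot(inherits(criteria, "gamma_criteria"))
  ref3 <- as_lattice3(reference)
  ev3 <- as_lattice3(evaluated)
  nd <- resolve_norm_dose(reference, criteria, norm_dose)

  refv <- ref3$values
  if (criteria$norm == "local") {
    dd_abs <- criteria$dose_tol / 100 * refv # zero-dose points yield NA
  } else {
    dd_abs <- criteria$dose_tol / 100 * nd
  }

  compute <- if (is.null(compute_mask)) rep(TRUE, length(refv))
             else as.logical(compute_mask)
  if (inherits(reference, "planar_dose"))
    compute <- compute & as.logical(reference$active)

  step <- criteria$dta / subsample
  radius <- radius_factor * criteria$dta
  g <- gamma_search_cpp(refv, as.integer(ref3$dim), ref3$spacing, ref3$origin,
                        ev3$values, as.integer(ev3$dim), ev3$spacing,
                        ev3$origin, dd_abs, criteria$dta, step, radius,
                        ref3$ndim, compute)
  shape <- if (ref3$ndim == 2L) ref3$dim[1:2] else ref3$dim
  gamma <- array(g, shape)
  evaluated_mask <- array(refv >= criteria$threshold & !is.na(g), shape)
  if (!any(evaluated_mask))
    warning("no reference points above the low-dose threshold: empty result")
  structure(
    list(gamma = gamma, evaluated = evaluated_mask, criteria = criteria,
         norm_dose = nd, subsample = subsample, radius = radius,
         spacing = ref3$spacing[seq_len(ref3$ndim)],
         origin = ref3$origin[seq_len(ref3$ndim)]),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %s points, %d counted (global)\n",
              paste(dim(x$gamma), collapse = " x "), sum(x$evaluated)))
  print(x$criteria)
  if (any(x$evaluated))
    cat(sprintf("  global pass rate: %.2f%%\n", 100 * pass_rate(x)))
  invisible(x)
}

#' Gamma pass rate
#'
#' Fraction of counted points with gamma <= 1 (boundary inclusive, with a
#' 1e-9 guard against floating-point round-off at exactly gamma = 1).
#' Without a mask, counted points are the result's `evaluated` mask — every
#' reference point whose planned dose exceeds the low-dose threshold (the
#' global convention). With a structure mask, *all* voxels inside the
#' structure contour are counted and the low-dose threshold is ignored.
#'
#' @param result a `gamma_result` from [compute_gamma()].
#' @param mask optional logical array on the reference geometry (a structure
#'   mask), or a structure name if `structures` is given.
#' @param structures optional [structure_set()] to look `mask` up in by name.
#' @return Pass fraction in `[0, 1]`.
#' @export
pass_rate <- function(result, mask = NULL, structures = NULL) {
  stopifnot(inherits(result, "gamma_result"))
  label <- "global"
  if (is.character(mask)) {
    if (is.null(structures)) stop("supply `structures` to look up mask by name")
    label <- mask
    mask <- structures$masks[[mask]]
    if (is.null(mask)) stop(sprintf("no structure named \"%s\"", label))
  }
  if (is.null(mask)) {
    counted <- result$evaluated
  } else {
    if (!identical(dim(mask), dim(result$gamma)))
      stop("mask does not match the reference geometry")
    counted <- mask & is.finite(result$gamma)
  }
  if (!any(counted))
    stop(sprintf("no counted points for \"%s\"", label))
  mean(result$gamma[counted] <= 1 + 1e-9)
}

#' Lattice quantization bound of the gamma search
#'
#' The search minimises the gamma objective over a displacement lattice of
#' spacing h rather than the continuum. The objective is Lipschitz in the
#' displacement with constant sqrt(1/dta^2 + (G/dD)^2), G the maximum
#' spatial gradient of the evaluated dose, so the lattice minimum exceeds
#' the continuum minimum by at most h*sqrt(ndim)/2 times that constant.
#'
#' @param evaluated the evaluated [dose_grid()] or [planar_dose()].
#' @param criteria a [gamma_criteria()].
#' @param norm_dose normalization dose in cGy (the one used in the search).
#' @param subsample lattice refinement used (step = dta/subsample).
#' @return Upper bound (dimensionless gamma units) on the quantization error.
#' @export
gamma_lattice_bound <- function(evaluated, criteria, norm_dose,
                                subsample = 10) {
  ev3 <- as_lattice3(evaluated)
  v <- array(ev3$values, ev3$dim)
  gmax <- 0
  for (a in seq_len(ev3$ndim)) {
    d <- dim(v)[a]
    if (d < 2) next
    dif <- abs(apply(v, setdiff(1:3, a), diff)) / ev3$spacing[a]
    gmax <- max(gmax, dif)
  }
  dd <- criteria$dose_tol / 100 * norm_dose
  h <- criteria$dta / subsample
  h * sqrt(ev3$ndim) / 2 * sqrt(1 / criteria$dta^2 + (gmax / dd)^2)
}
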