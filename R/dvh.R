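#' Cumulative dose-volume histogram of a structure
#'
#' Builds the exact (voxel-list) cumulative DVH of a structure: no histogram
#' binning is applied, so every dose-volume query is answered from the sorted
#' voxel doses directly. The curve V(d) is the fraction of the structure
#' volume receiving at least dose d; it is monotone non-increasing, equals 1
#' at d = 0 and 0 above the maximum voxel dose.
#'
#' @param dose a [dose_grid()].
#' @param mask logical array matching the grid (the structure), or a
#'   structure name if `structures` is given.
#' @param structures optional [structure_set()] for name lookup.
#' @param structure label stored on the curve.
#' @return An object of class `dvh_curve`: sorted voxel doses (cGy), the
#'   uniform per-voxel volume (cc) and total volume (cc).
#' @export
cumulative_dvh <- function(dose, mask, structures = NULL,
                           structure = NULL) {
  stopifnot(inherits(dose, "dose_grid"))
  if (is.character(mask)) {
    structure <- structure %||% mask
    if (is.null(structures)) stop("supply `structures` to look up mask by name")
    nm <- mask
    mask <- structures$masks[[nm]]
    if (is.null(mask)) stop(sprintf("no structure named \"%s\"", nm))
  }
  if (!identical(dim(mask), dim(dose$values)))
    stop("mask does not match the dose grid")
  if (!any(mask)) stop(sprintf("empty mask for \"%s\"", structure %||% "structure"))
  doses <- sort(dose$values[mask])
  vv <- voxel_volume_cc(dose)
  structure(
    list(structure = structure %||% "structure", doses = doses,
         voxel_cc = vv, total_cc = vv * length(doses)),
    class = "dvh_curve"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %d voxels, %.2f cc, dose [%.1f, %.1f] cGy\n",
              x$structure, length(x$doses), x$total_cc,
              min(x$doses), max(x$doses)))
  invisible(x)
}

#' Dose covering a volume fraction (Dv)
#'
#' D_v is the smallest dose received by the hottest fraction v of the
#' structure — e.g. `dose_at_volume(curve, 0.02)` is D2%, the near-maximum
#' dose. The value is obtained by linear interpolation between order
#' statistics of the voxel doses (the type-7 quantile convention: the
#' 1 - v sample quantile), which makes the rule exact for uniform doses and
#' reproducible for any voxel list.
#'
#' @param curve a `dvh_curve` from [cumulative_dvh()].
#' @param v volume fraction in (0, 1]; `v = 1` returns the minimum voxel dose.
#' @return Dose in cGy.
#' @export
dose_at_volume <- function(curve, v) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (any(!is.finite(v)) || any(v <= 0) || any(v > 1))
    stop("`v` must lie in (0, 1]")
  stats::quantile(curve$doses, probs = 1 - v, type = 7, names = FALSE)
}

#' Volume fraction receiving at least a dose (Vd)
#'
#' Fraction of the structure volume receiving >= d (boundary inclusive:
#' voxels at exactly d count). `pct` expresses the query as a percentage of
#' the prescribed dose, e.g. `pct = 95` for V95%; the prescription level is
#' the structure's own entry in a [prescription()] when available, else its
#' normalization dose.
#'
#' @param curve a `dvh_curve`.
#' @param dose absolute query dose in cGy (give exactly one of `dose`, `pct`).
#' @param pct query as percent of prescription.
#' @param prescription a [prescription()] or a single dose in cGy; required
#'   with `pct`.
#' @return Volume fraction in `[0, 1]`.
#' @export
volume_at_dose <- function(curve, dose = NULL, pct = NULL,
                           prescription = NULL) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (is.null(dose) == is.null(pct))
    stop("give exactly one of `dose` or `pct`")
  if (!is.null(pct)) {
    if (is.null(prescription))
      stop("percent query needs a `prescription`")
    dose <- pct / 100 * rx_level(prescription, curve$structure)
  }
  if (!is.finite(dose) || dose < 0) stop("query dose must be >= 0 (cGy)")
  mean(curve$doses >= dose)
}

# Prescribed dose level (cGy) for one structure: its own entry when present,
# else the prescription's normalization dose; numerics pass through.
rx_level <- function(prescription, structure) {
  if (inherits(prescription, "prescription")) {
    lev <- prescription$doses[[structure]] %||% NULL
    if (is.null(lev) || is.na(lev)) prescription$normalization else lev
  } else as.double(prescription)
}

#' Homogeneity index of a target dose
#'
#' HI = (D2% - D98%) / D50%: the spread between the near-maximum and
#' near-minimum target doses relative to the median dose. 0 means a
#' perfectly uniform target dose; larger values mean less homogeneous.
#' Invariant under global dose scaling.
#'
#' @param x a `dvh_curve`, or a named list/vector with `D2`, `D50`, `D98`
#'   (cGy).
#' @return HI (dimensionless, >= 0 for any real dose distribution).
#' @export
homogeneity_index <- function(x) {
  if (inherits(x, "dvh_curve")) {
    d2 <- dose_at_volume(x, 0.02)
    d50 <- dose_at_volume(x, 0.50)
    d98 <- dose_at_volume(x, 0.98)
  } else {
    d2 <- x[["D2"]]; d50 <- x[["D50"]]; d98 <- x[["D98"]]
  }
  if (!is.finite(d50) || d50 == 0) stop("D50% is zero: HI undefined")
  (d2 - d98) / d50
}

#' Conformity index of a target dose
#'
#' CI = (PTV95% / PTV) x (PTV95% / V95%), where PTV95% is the target
#' sub-volume receiving at least 95% of the prescribed dose, PTV the target
#' volume and V95% the total evaluated volume receiving at least 95% of the
#' prescribed dose. The first factor is target coverage, the second
#' selectivity; CI = 1 iff the 95% isodose exactly conforms to the target.
#'
#' @param dose a [dose_grid()].
#' @param ptv logical target mask, or a structure name with `structures`.
#' @param prescription prescribed dose for this target: cGy or a
#'   [prescription()] (the target's own level is used).
#' @param eval_mask optional logical mask limiting the V95% volume (e.g. the
#'   body contour); default: the whole grid.
#' @param structures optional [structure_set()] for name lookup.
#' @param level isodose level as a fraction of prescription (default 0.95).
#' @return CI in `[0, 1]`; 0 (with a warning) when no voxel reaches the
#'   isodose level.
#' @export
conformity_index <- function(dose, ptv, prescription, eval_mask = NULL,
                             structures = NULL, level = 0.95) {
  stopifnot(inherits(dose, "dose_grid"))
  nm <- "PTV"
  if (is.character(ptv)) {
    nm <- ptv
    if (is.null(structures)) stop("supply `structures` to look up mask by name")
    ptv <- structures$masks[[nm]]
    if (is.null(ptv)) stop(sprintf("no structure named \"%s\"", nm))
  }
  if (!any(ptv)) stop("empty PTV mask")
  rx <- rx_level(prescription, nm)
  if (!is.finite(rx) || rx <= 0) stop("prescription must be positive")
  thr <- level * rx
  hot <- dose$values >= thr
  if (is.null(eval_mask)) v95 <- sum(hot) else v95 <- sum(hot & eval_mask)
  ptv95 <- sum(hot & ptv)
  if (v95 == 0) {
    warning("no voxel reaches the isodose level: CI set to 0")
    return(0)
  }
  (ptv95 / sum(ptv)) * (ptv95 / v95)
}

#' Standard dose-volume metric set for one structure
#'
#' Computes the DVH parameters used in plan-vs-delivery comparison: D2%,
#' D50%, D95%, D98%, Dmean (cGy), V100% and V95% (fractions of the structure
#' volume at the prescription level), HI, and — when the structure is a
#' target with a prescription — CI.
#'
#' @param dose a [dose_grid()].
#' @param mask structure mask or name (with `structures`).
#' @param prescription a [prescription()] or dose in cGy; `NULL` skips the
#'   prescription-relative metrics (V100%, V95%, CI).
#' @param eval_mask optional body mask for the CI denominator.
#' @param structures optional [structure_set()] for name lookup.
#' @param structure label for the metric row.
#' @return Named list of metrics (class `metric_set`).
#' @export
metric_set <- function(dose, mask, prescription = NULL, eval_mask = NULL,
                       structures = NULL, structure = NULL) {
  curve <- cumulative_dvh(dose, mask, structures, structure)
  m <- list(
    structure = curve$structure,
    D2 = dose_at_volume(curve, 0.02),
    D50 = dose_at_volume(curve, 0.50),
    D95 = dose_at_volume(curve, 0.95),
    D98 = dose_at_volume(curve, 0.98),
    Dmean = mean(curve$doses)
  )
  m$HI <- homogeneity_index(list(D2 = m$D2, D50 = m$D50, D98 = m$D98))
  if (!is.null(prescription)) {
    m$V100 <- volume_at_dose(curve, pct = 100, prescription = prescription)
    m$V95 <- volume_at_dose(curve, pct = 95, prescription = prescription)
    msk <- if (is.character(mask)) structures$masks[[mask]] else mask
    m$CI <- conformity_index(dose, msk, rx_level(prescription, curve$structure),
                             eval_mask = eval_mask)
  }
  structure(m, class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> %s\n", x$structure))
  for (nm in setdiff(names(x), "structure"))
    cat(sprintf("  %-6s %s\n", nm, format(x[[nm]], digits = 6)))
  invisible(x)
}

#' Relative deviation of a reconstructed value from its plan
#'
#' Delta = 100 x (reconstructed - planned) / planned, in percent; negative
#' values are decrements of the delivered/reconstructed quantity relative to
#' the plan.
#'
#' @param reconstructed,planned numeric (vectorised); `planned` must be
#'   non-zero.
#' @return Deviation(s) in percent.
#' @export
relative_deviation <- function(reconstructed, planned) {
  if (any(planned == 0)) stop("planned value is zero: relative deviation undefined")
  100 * (reconstructed - planned) / planned
}

#' Summarise per-case deviations with a one-sample t-test
#'
#' Range, mean +/- sample standard deviation (n - 1 denominator), and the
#' two-sided p-value of the one-sample t-test of mean zero
#' (t = mean / (s / sqrt(n)), df = n - 1). A degenerate all-equal sample has
#' p = 1 when its mean is 0 (no evidence of deviation, by convention) and an
#' undefined t otherwise (p = NA with a warning).
#'
#' @param deviations numeric vector of per-case deviations (%), n >= 2.
#' @return Object of class `deviation_summary`: `n`, `min`, `max`, `mean`,
#'   `sd`, `t`, `df`, `p`.
#' @export
deviation_summary <- function(deviations) {
  deviations <- as.double(deviations)
  if (length(deviations) < 2 || any(!is.finite(deviations)))
    stop("need >= 2 finite deviations")
  n <- length(deviations)
  m <- mean(deviations)
  s <- stats::sd(deviations)
  if (s == 0) {
    if (m == 0) {
      t <- 0; p <- 1
    } else {
      warning("zero variance with non-zero mean: t undefined")
      t <- NA_real_; p <- NA_real_
    }
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  structure(list(n = n, min = min(deviations), max = max(deviations),
                 mean = m, sd = s, t = t, df = n - 1, p = p),
            class = "deviation_summary")
}

#' @export
print.deviation_summary <- function(x, ...) {
  cat(sprintf("<deviation_summary> n = %d, range [%.2f, %.2f], %.2f +/- %.2f, P = %.4g\n",
              x$n, x$min, x$max, x$mean, x$sd, x$p))
  invisible(x)
}
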