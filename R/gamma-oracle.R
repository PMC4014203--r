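#' Brute-force gamma oracle
#'
#' Reference implementation of the gamma index for validating
#' [compute_gamma()]: an exhaustive scan of the *entire* displacement lattice
#' (no early exit, no pruning) written in vectorised R with its own
#' interpolation path. With `fine = 1` it scans exactly the lattice the fast
#' search uses, so the two must agree to floating-point accuracy; with
#' `fine > 1` it scans a `fine`-times denser lattice and can only find equal
#' or smaller minima, within [gamma_lattice_bound()] of the coarse result.
#'
#' Intended for small inputs only; refuses anything above 64 points per axis.
#'
#' @inheritParams compute_gamma
#' @param fine lattice refinement factor relative to the fast search
#'   (step = `dta / (subsample * fine)`).
#' @return A `gamma_result` (see [compute_gamma()]).
#' @export
gamma_oracle <- function(reference, evaluated, criteria = gamma_criteria(),
                         norm_dose = NULL, fine = 1, subsample = 10,
                         radius_factor = 3, compute_mask = NULL) {
  stopifnot(inherits(criteria, "gamma_criteria"))
  ref3 <- as_lattice3(reference)
  if (any(ref3$dim > 64L))
    stop("gamma_oracle is a brute-force check: inputs must be <= 64 points per axis")
  nd <- resolve_norm_dose(reference, criteria, norm_dose)
  step <- criteria$dta / (subsample * fine)
  radius <- radius_factor * criteria$dta
  m <- ceiling(radius / step)
  r2max <- radius^2 * (1 + 1e-12) + 1e-12

  planar <- inherits(reference, "planar_dose")
  if (planar) {
    offs <- as.matrix(expand.grid(dx = (-m:m) * step, dy = (-m:m) * step,
                                  KEEP.OUT.ATTRS = FALSE))
    evp <- evaluated
    evp$values[!evp$active] <- 0
    interp <- function(pts) interp_bilinear(evp, pts)
    naxes <- 2L
  } else {
    offs <- as.matrix(expand.grid(dx = (-m:m) * step, dy = (-m:m) * step,
                                  dz = (-m:m) * step, KEEP.OUT.ATTRS = FALSE))
    interp <- function(pts) interp_trilinear(evaluated, pts)
    naxes <- 3L
  }
  d2 <- rowSums(offs^2)
  keep <- d2 <= r2max
  offs <- offs[keep, , drop = FALSE]
  s2 <- d2[keep] / criteria$dta^2

  refv <- ref3$values
  dd_abs <- if (criteria$norm == "local") criteria$dose_tol / 100 * refv
            else rep(criteria$dose_tol / 100 * nd, length(refv))
  compute <- if (is.null(compute_mask)) rep(TRUE, length(refv))
             else as.logical(compute_mask)
  if (planar) compute <- compute & as.logical(reference$active)

  shape <- ref3$dim[seq_len(naxes)]
  gamma <- array(NA_real_, shape)
  idx <- which(compute & dd_abs > 0)
  pos0 <- arrayInd(idx, ref3$dim)[, seq_len(naxes), drop = FALSE]
  pos0 <- sweep(sweep(pos0 - 1, 2, ref3$spacing[seq_len(naxes)], "*"),
                2, ref3$origin[seq_len(naxes)], "+")
  for (q in seq_along(idx)) {
    pts <- sweep(offs, 2, pos0[q, ], "+")
    ir <- interp(pts)
    g2 <- s2 + ((ir$values - refv[idx[q]]) / dd_abs[idx[q]])^2
    g2 <- g2[ir$inside]
    if (length(g2)) gamma[idx[q]] <- sqrt(min(g2))
  }
  evaluated_mask <- array(refv >= criteria$threshold & !is.na(gamma), shape)
  structure(
    list(gamma = gamma, evaluated = evaluated_mask, criteria = criteria,
         norm_dose = nd, subsample = subsample * fine, radius = radius,
         spacing = ref3$spacing[seq_len(naxes)],
         origin = ref3$origin[seq_len(naxes)]),
    class = "gamma_result"
  )
}
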