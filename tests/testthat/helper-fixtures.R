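# Shared in-code fixtures: every object is generated here at test time.

coord_arrays <- function(grid) {
  ax <- grid_axes(grid)
  d <- dim(grid$values)
  list(X = array(ax$x, d),
       Y = array(rep(ax$y, each = d[1]), d),
       Z = array(rep(ax$z, each = d[1] * d[2]), d))
}

# closed polygon approximating a circle
circle_poly <- function(radius, center = c(0, 0), n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  p <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
  p[nrow(p), ] <- p[1, ]
  p
}

# contour stack of a sphere, slices aligned to the grid's voxel-center layers
sphere_contours <- function(radius, grid, center = c(0, 0, 0)) {
  ax <- grid_axes(grid)
  zs <- ax$z[abs(ax$z - center[3]) < radius]
  lapply(zs, function(z) {
    list(z = z, xy = circle_poly(sqrt(radius^2 - (z - center[3])^2),
                                 center[1:2]))
  })
}

# rasterized 20 mm sphere at 1 mm spacing carrying a linear radial dose ramp
# 0 -> 100 cGy (exactly 100 at the surface radius)
ramp_sphere <- function(radius = 20, spacing = 1) {
  grid <- make_phantom(spacing, dims_cm = rep(2.2 * radius / 10, 3))
  ss <- rasterize_contours(list(ball = sphere_contours(radius, grid)), grid)
  co <- coord_arrays(grid)
  r <- sqrt(co$X^2 + co$Y^2 + co$Z^2)
  dose <- dose_grid(pmin(r / radius, 1) * 100, grid$spacing, grid$origin)
  list(dose = dose, mask = ss$masks$ball, grid = grid)
}

# 1D dose gradient of `grad_pct` %/mm of D0 along x, constant along y;
# evaluated = the same field rigidly shifted by `shift_mm`
gradient_pair <- function(shift_mm = 3, D0 = 100, grad_pct = 1,
                          n = 41, m = 21, pitch = 1) {
  x <- (seq_len(n) - 1) * pitch - (n - 1) * pitch / 2
  f <- function(offset) {
    vals <- matrix(D0 + grad_pct / 100 * D0 * (x - offset), n, m)
    planar_dose(vals, pitch, origin = c(x[1], 0))
  }
  list(ref = f(0), ev = f(shift_mm))
}

random_planar_pair <- function(n = 20, pitch = 5, base = 100, sd = 5) {
  ref <- planar_dose(matrix(base + stats::rnorm(n * n, 0, sd), n, n), pitch)
  ev <- planar_dose(matrix(base + stats::rnorm(n * n, 0, sd), n, n), pitch)
  list(ref = ref, ev = ev)
}

# gamma_result wrapper around a literal gamma map (for pass-rate arithmetic)
literal_gamma_result <- function(gamma, evaluated = NULL) {
  gamma <- as.matrix(gamma)
  if (is.null(evaluated)) evaluated <- array(TRUE, dim(gamma))
  structure(list(gamma = gamma, evaluated = evaluated,
                 criteria = gamma_criteria(), norm_dose = 100,
                 subsample = 10, radius = 9,
                 spacing = c(1, 1), origin = c(0, 0)),
            class = "gamma_result")
}

# small scenario for end-to-end runs: coarser grid keeps unit tests quick
test_scenario <- function(cases = 2L, seed = 7L, spacing = 6) {
  cfg <- default_scenario()
  cfg$cases <- cases
  cfg$seed <- seed
  cfg$spacing_mm <- spacing
  cfg
}
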