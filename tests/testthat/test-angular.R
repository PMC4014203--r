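test_that("a central detector always sees the gantry angle itself", {
  th <- 0:359
  expect_equal(incident_angle(0, th, 1000), as.double(th))
})

test_that("incident angle handles off-axis offsets and quadrants", {
  expect_equal(incident_angle(100, 0, 1000), atan(0.1) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(incident_angle(100, 0, 1000), 5.7106, tolerance = 1e-4)
  # denominator zero, numerator positive
  expect_equal(incident_angle(-76.2, 90, 1000), 90)
  # two-argument arctangent oracle across quadrants
  for (th in c(90, 180, 270)) for (d in c(-80, 0, 80)) {
    tr <- th * pi / 180
    oracle <- (atan2(d + 1000 * sin(tr), 1000 * cos(tr)) * 180 / pi) %% 360
    expect_equal(incident_angle(d, th, 1000), oracle, tolerance = 1e-12)
  }
  expect_error(incident_angle(0, 0, -1), "SAD")
})

test_that("the sampling grid refines to 1 degree around lateral incidence", {
  g <- angle_sampling_grid()
  expect_true(all(diff(g) > 0))
  expect_true(all(g >= 0 & g < 360))
  expect_true(all(c(86, 87, 93, 94, 266, 274) %in% g))
  expect_false(any(c(42, 101) %in% g))
  expect_equal(g[1], 0)
})

test_that("correction factors are calc/meas ratios normalized at zero", {
  a <- c(0, 90, 180, 270)
  expect_equal(build_correction_table(a, c(10, 10, 10, 10),
                                      c(10, 10, 10, 10))$factors,
               rep(1, 4))
  # measured = calculated x R  =>  factor = 1/R
  R <- c(1, 0.8, 0.95, 0.8)
  tab <- build_correction_table(a, c(10, 10, 10, 10) * R, c(10, 10, 10, 10))
  expect_equal(tab$factors, 1 / R, tolerance = 1e-12)
  # 2% under-response at 180 degrees
  tab2 <- build_correction_table(c(0, 180), c(100, 98), c(100, 100))
  expect_equal(tab2$factors[2], 1 / 0.98, tolerance = 1e-9)
  expect_equal(tab2$factors[2], 1.0204, tolerance = 1e-4)

  expect_error(build_correction_table(c(5, 10), c(1, 1), c(1, 1)),
               "0-degree")
  expect_error(build_correction_table(c(0, 10), c(1, -1), c(1, 1)),
               "positive")
  expect_error(correction_table(c(0, 10), c(1.01, 1)), "normalization")
})

test_that("factor interpolation is linear and periodic across 360", {
  tab <- correction_table(c(0, 5, 355), c(1, 1.02, 1.04))
  expect_equal(correction_factor_at(tab, 5), 1.02)
  expect_equal(correction_factor_at(tab, 2.5), 1.01)
  expect_equal(correction_factor_at(tab, 357.5), 1.02) # wraps to the 0 sample
  expect_equal(correction_factor_at(tab, -2.5), 1.02)  # negative angles wrap
})

test_that("per-detector correction composes offset geometry with the table", {
  vals <- matrix(100, 32, 32)
  frame <- planar_dose(vals, 7.62, origin = -c(31, 31) * 7.62 / 2,
                       gantry_angle = 0)
  ident <- correction_table(c(0, 180), c(1, 1))
  expect_equal(apply_correction(frame, ident)$values, vals)

  tab <- correction_table(c(0, 90, 180, 270), c(1, 1.25, 1.02, 1.25))
  corr <- apply_correction(frame, tab)
  d <- frame$origin[1] + (0:31) * 7.62 - 0 # center at 0: offsets are the axis
  phi <- incident_angle(d, 0, 1000)
  expect_equal(corr$values[, 7], 100 * correction_factor_at(tab, phi),
               tolerance = 1e-12)
  # detectors in one row share the offset, hence the factor
  expect_true(all(apply(corr$values, 1, function(r) diff(range(r)) == 0)))
  expect_error(apply_correction(planar_dose(vals, 7.62), tab),
               "no gantry angle")
})

test_that("response simulation and correction invert each other", {
  model <- response_model(A = 0.2, w = 10, ripple = 0.005)
  expect_equal(response_at(model, 0), 1)
  angles <- angle_sampling_grid()
  tab <- build_correction_table(angles, 100 * response_at(model, angles),
                                rep(100, length(angles)))
  vals <- matrix(150, 32, 32)
  for (th in c(0, 45, 88, 90, 135, 272)) {
    frame <- planar_dose(vals, 7.62, origin = -c(31, 31) * 7.62 / 2,
                         gantry_angle = th)
    meas <- simulate_angular_response(frame, model)
    corr <- apply_correction(meas, tab)
    expect_lt(max(abs(corr$values / vals - 1)), 0.005)
  }
})

test_that("composite correction is linear over frames", {
  model <- response_model()
  ang <- angle_sampling_grid()
  tab <- build_correction_table(ang, 100 * response_at(model, ang),
                                rep(100, length(ang)))
  set.seed(2)
  mk <- function(th) planar_dose(matrix(runif(64, 50, 150), 8, 8), 7.62,
                                 origin = c(-26.67, -26.67),
                                 gantry_angle = th)
  frames <- lapply(c(0, 120, 240), mk)
  corr_then_sum <- sum_planar(lapply(frames, apply_correction, table = tab))
  # correcting the per-frame sum at a single angle is only defined per
  # frame; linearity within one angle:
  a <- mk(75); b <- mk(75)
  both <- sum_planar(list(a, b))
  both$gantry_angle <- 75
  expect_equal(apply_correction(both, tab)$values,
               apply_correction(a, tab)$values + apply_correction(b, tab)$values,
               tolerance = 1e-12)
  expect_true(is.na(corr_then_sum$gantry_angle))
})
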