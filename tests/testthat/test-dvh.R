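test_that("cumulative DVH answers exact voxel-list queries", {
  g <- dose_grid(array(7000, c(4, 4, 4)), c(2, 2, 2), c(0, 0, 0))
  mask <- array(TRUE, c(4, 4, 4))
  cv <- cumulative_dvh(g, mask, structure = "PTV")
  expect_equal(volume_at_dose(cv, dose = 0), 1)
  expect_equal(volume_at_dose(cv, dose = 7000), 1) # boundary inclusive
  expect_equal(volume_at_dose(cv, dose = 7000.1), 0)
  expect_equal(dose_at_volume(cv, 0.3), 7000)

  v <- array(0, c(2, 1, 1)); v[1] <- 60; v[2] <- 100
  g2 <- dose_grid(v, c(1, 1, 1), c(0, 0, 0))
  cv2 <- cumulative_dvh(g2, array(TRUE, c(2, 1, 1)))
  expect_equal(volume_at_dose(cv2, dose = 80), 0.5)

  expect_error(cumulative_dvh(g, array(FALSE, c(4, 4, 4))), "empty mask")
})

test_that("Dv interpolates between order statistics", {
  v <- array(as.double(1:100), c(100, 1, 1))
  cv <- cumulative_dvh(dose_grid(v, c(1, 1, 1), c(0, 0, 0)),
                       array(TRUE, c(100, 1, 1)))
  expect_equal(dose_at_volume(cv, 0.50), 50.5)
  expect_equal(dose_at_volume(cv, 1), 1)   # minimum voxel dose
  expect_equal(dose_at_volume(cv, 0.02), 98.02)
  expect_error(dose_at_volume(cv, 0), "\\(0, 1\\]")
  expect_error(dose_at_volume(cv, 1.2), "\\(0, 1\\]")
})

test_that("DVH of a radial ramp in a rasterized sphere matches closed forms", {
  rs <- ramp_sphere()
  cv <- cumulative_dvh(rs$dose, rs$mask)
  d50 <- dose_at_volume(cv, 0.50)
  expect_lt(abs(d50 - 100 * 0.5^(1 / 3)) / (100 * 0.5^(1 / 3)), 0.02)
  expect_lt(abs(mean(cv$doses) - 75) / 75, 0.02)
  # V(50) = 1 - (1/2)^3 of the ball volume
  expect_lt(abs(volume_at_dose(cv, dose = 50) - (1 - 0.5^3)), 0.02)
  # Dmean equals the arithmetic voxel mean exactly
  expect_identical(mean(cv$doses), mean(rs$dose$values[rs$mask]))
})

test_that("dose_at_volume and volume_at_dose are near-mutual inverses", {
  set.seed(13)
  v <- array(sort(runif(500, 10, 90)), c(500, 1, 1))
  cv <- cumulative_dvh(dose_grid(v, c(1, 1, 1), c(0, 0, 0)),
                       array(TRUE, c(500, 1, 1)))
  for (vol in c(0.1, 0.25, 0.5, 0.8, 0.95))
    expect_lt(abs(volume_at_dose(cv, dose = dose_at_volume(cv, vol)) - vol),
              1 / 500 + 1e-12)
})

test_that("percent volume queries resolve against the prescription", {
  rx <- prescription(c(PTVnx = 7000, PTV1 = 6600))
  v <- array(c(0.90, 0.95, 1.00, 1.05) * 7000, c(4, 1, 1))
  cv <- cumulative_dvh(dose_grid(v, c(1, 1, 1), c(0, 0, 0)),
                       array(TRUE, c(4, 1, 1)), structure = "PTVnx")
  expect_equal(volume_at_dose(cv, pct = 95, prescription = rx), 0.75)
  expect_equal(volume_at_dose(cv, pct = 100, prescription = rx), 0.5)
  expect_error(volume_at_dose(cv, pct = 95), "prescription")
  expect_error(volume_at_dose(cv, dose = 1, pct = 1, prescription = rx),
               "exactly one")
})

test_that("homogeneity index: uniform zero, arithmetic, scale invariance", {
  g <- dose_grid(array(7000, c(3, 3, 3)), c(2, 2, 2), c(0, 0, 0))
  cv <- cumulative_dvh(g, array(TRUE, c(3, 3, 3)))
  expect_identical(homogeneity_index(cv), 0)
  expect_equal(homogeneity_index(list(D2 = 74.8, D98 = 66.2, D50 = 70.0)),
               0.122857, tolerance = 1e-5)
  expect_identical(homogeneity_index(list(D2 = 149.6, D98 = 132.4, D50 = 140)),
                   homogeneity_index(list(D2 = 74.8, D98 = 66.2, D50 = 70)))
  expect_error(homogeneity_index(list(D2 = 1, D98 = 0, D50 = 0)), "D50")
})

test_that("conformity index multiplies coverage and selectivity", {
  # 1 cc voxels: PTV = 100 cc, of which 95 reach the 95% level; 25 more
  # hot voxels outside, so V95 = 120 cc -> CI = (95/100) x (95/120)
  v <- array(0, c(15, 10, 1))
  ptv <- array(FALSE, c(15, 10, 1))
  ptv[1:10, 1:10, 1] <- TRUE
  v[ptv] <- 100
  v[1:5, 1, 1] <- 10                       # 5 cold PTV voxels
  v[11:15, 1:5, 1] <- 100                  # 25 hot voxels outside the PTV
  g <- dose_grid(v, c(10, 10, 10), c(0, 0, 0))
  ci <- conformity_index(g, ptv, prescription = 100, level = 0.95)
  expect_equal(ci, (95 / 100) * (95 / 120), tolerance = 1e-12)
  expect_equal(ci, 0.752083, tolerance = 1e-6)

  # perfectly conformal: hot region coincides with the PTV
  v2 <- array(0, c(6, 6, 1)); v2[2:5, 2:5, 1] <- 100
  ptv2 <- v2 > 0
  g2 <- dose_grid(v2, c(10, 10, 10), c(0, 0, 0))
  expect_identical(conformity_index(g2, ptv2, prescription = 100), 1)
  # scaling dose and prescription together changes nothing
  g3 <- dose_grid(2 * v2, c(10, 10, 10), c(0, 0, 0))
  expect_equal(conformity_index(g3, ptv2, prescription = 200),
               conformity_index(g2, ptv2, prescription = 100),
               tolerance = 1e-12)
  # nothing reaches the level
  expect_warning(ci0 <- conformity_index(g2, ptv2, prescription = 1e6),
                 "CI set to 0")
  expect_identical(ci0, 0)
})

test_that("relative deviation is a plain percent difference", {
  expect_equal(relative_deviation(2.1, 2.0), 5)
  expect_equal(relative_deviation(3, 3), 0)
  expect_equal(relative_deviation(67.55, 100), -32.45)
  expect_error(relative_deviation(1, 0), "zero")
})

test_that("deviation_summary reproduces the one-sample t-test", {
  s <- deviation_summary(1:5)
  expect_equal(s$mean, 3)
  expect_equal(s$sd, 1.58114, tolerance = 1e-5)
  expect_equal(s$t, 4.24264, tolerance = 1e-5)
  expect_equal(s$df, 4)
  expect_equal(round(s$p, 5), 0.01324)

  z <- deviation_summary(c(0, 0, 0))
  expect_identical(z$p, 1)
  expect_identical(deviation_summary(c(-1, 1))$p, 1)
  expect_warning(nv <- deviation_summary(c(2, 2, 2)), "t undefined")
  expect_true(is.na(nv$p))
  expect_error(deviation_summary(3), ">= 2")
})

test_that("deviation t-test agrees with stats::t.test on random samples", {
  set.seed(99)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
    s <- deviation_summary(x)
    ref <- stats::t.test(x)
    expect_equal(s$p, unname(ref$p.value), tolerance = 1e-9)
    expect_equal(s$t, unname(ref$statistic), tolerance = 1e-9)
  }
})

test_that("metric_set bundles the table parameters coherently", {
  rs <- ramp_sphere()
  rx <- prescription(c(ball = 80))
  m <- metric_set(rs$dose, rs$mask, rx, structure = "ball")
  expect_true(m$D2 >= m$D50 && m$D50 >= m$D98)
  expect_true(m$CI >= 0 && m$CI <= 1)
  expect_true(m$HI >= 0)
  expect_equal(m$V95, volume_at_dose(cumulative_dvh(rs$dose, rs$mask,
                                                    structure = "ball"),
                                     dose = 76))
})
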