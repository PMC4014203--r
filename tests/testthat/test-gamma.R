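test_that("identical fields give gamma zero everywhere and full pass", {
  set.seed(1)
  p <- planar_dose(matrix(100 + runif(400) * 40, 20, 20), pitch = 5)
  r <- compute_gamma(p, p)
  expect_true(all(r$gamma == 0))
  expect_equal(pass_rate(r), 1)

  g <- dose_grid(array(50 + runif(5 * 5 * 5) * 10, c(5, 5, 5)), c(3, 3, 3),
                 c(0, 0, 0))
  r3 <- compute_gamma(g, g, gamma_criteria(norm = "prescription"),
                      norm_dose = 60)
  expect_true(all(r3$gamma == 0))
})

test_that("a uniform +3% offset sits exactly on the gamma = 1 boundary", {
  D0 <- 200
  a <- planar_dose(matrix(D0, 20, 20), pitch = 5)
  b <- planar_dose(matrix(1.03 * D0, 20, 20), pitch = 5)
  r <- compute_gamma(a, b, gamma_criteria(norm = "prescription"),
                     norm_dose = D0)
  expect_equal(max(abs(r$gamma - 1)), 0, tolerance = 1e-9)
  expect_equal(pass_rate(r), 1) # boundary counts as pass
})

test_that("3 mm shift of a 1%/mm gradient yields interior gamma sqrt(2)/2", {
  gp <- gradient_pair(shift_mm = 3)
  r <- compute_gamma(gp$ref, gp$ev, gamma_criteria(norm = "prescription"),
                     norm_dose = 100)
  interior <- r$gamma[11:31, 6:16]
  expect_equal(as.vector(interior), rep(sqrt(2) / 2, length(interior)),
               tolerance = 0.01)
})

test_that("fast search matches the exhaustive oracle on random pairs", {
  set.seed(23)
  for (i in 1:5) {
    pair <- random_planar_pair()
    fast <- compute_gamma(pair$ref, pair$ev)
    slow <- gamma_oracle(pair$ref, pair$ev)
    expect_lt(max(abs(fast$gamma - slow$gamma)), 1e-6)
  }
})

test_that("a finer oracle lattice only lowers gamma, within the bound", {
  set.seed(31)
  pair <- random_planar_pair()
  crit <- gamma_criteria()
  coarse <- compute_gamma(pair$ref, pair$ev, crit)
  fine <- gamma_oracle(pair$ref, pair$ev, crit, fine = 3)
  bound <- gamma_lattice_bound(pair$ev, crit, coarse$norm_dose, subsample = 10)
  expect_true(all(fine$gamma <= coarse$gamma + 1e-9))
  expect_true(all(coarse$gamma - fine$gamma <= bound + 1e-9))
})

test_that("gamma is invariant under joint dose/normalization scaling", {
  set.seed(5)
  pair <- random_planar_pair()
  crit <- gamma_criteria(norm = "prescription", threshold = 0)
  r1 <- compute_gamma(pair$ref, pair$ev, crit, norm_dose = 100)
  k <- 7.5
  ref2 <- planar_dose(k * pair$ref$values, pair$ref$pitch, pair$ref$origin)
  ev2 <- planar_dose(k * pair$ev$values, pair$ev$pitch, pair$ev$origin)
  r2 <- compute_gamma(ref2, ev2, crit, norm_dose = k * 100)
  expect_equal(r2$gamma, r1$gamma, tolerance = 1e-12)
})

test_that("gamma never exceeds the zero-displacement dose term", {
  set.seed(9)
  pair <- random_planar_pair()
  r <- compute_gamma(pair$ref, pair$ev)
  dd <- 0.03 * max(pair$ref$values)
  zero_disp <- abs(pair$ev$values - pair$ref$values) / dd
  expect_true(all(r$gamma <= zero_disp + 1e-12))
})

test_that("enlarging either criterion never lowers the pass rate", {
  set.seed(41)
  grid <- make_phantom(6, dims_cm = c(12, 12, 6))
  co <- coord_arrays(grid)
  ball <- sqrt(co$X^2 + co$Y^2 + co$Z^2) <= 40
  ss <- structure_set(list(t = ball), grid)
  rx <- prescription(c(t = 200))
  plan <- make_planned_dose(ss, rx, sigma = 4)
  pert <- perturb_dose(plan, perturbation_spec(shift = c(2, 1, 0),
                                               scale = 1.02, seed = 2))
  rates <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    crit <- gamma_criteria(dose_tol = i, dta = j, norm = "prescription",
                           threshold = 20)
    rates[i, j] <- pass_rate(compute_gamma(plan, pert, crit, norm_dose = 200,
                                           subsample = 6))
  }
  expect_true(all(diff(rates) >= 0))     # dose tolerance up
  expect_true(all(t(diff(t(rates))) >= 0)) # dta up
})

test_that("pass_rate counts gamma <= 1 inclusively and checks masks", {
  r <- literal_gamma_result(matrix(c(0.2, 0.9, 1.0, 1.1), 2, 2))
  expect_equal(pass_rate(r), 0.75)
  expect_equal(pass_rate(literal_gamma_result(matrix(0, 3, 3))), 1)
  expect_error(pass_rate(r, matrix(FALSE, 2, 2)), "no counted points")
  expect_error(pass_rate(r, matrix(TRUE, 3, 3)), "does not match")
})

test_that("structure pass rates ignore the low-dose threshold", {
  gp <- gradient_pair(shift_mm = 3)
  crit <- gamma_criteria(norm = "prescription", threshold = 1e5)
  expect_warning(r <- compute_gamma(gp$ref, gp$ev, crit, norm_dose = 100),
                 "empty result")
  expect_error(pass_rate(r), "no counted points") # global counts nothing
  mask <- matrix(FALSE, nrow(r$gamma), ncol(r$gamma))
  mask[11:31, 6:16] <- TRUE
  expect_equal(pass_rate(r, mask), 1) # all interior gamma < 1
})

test_that("local normalization uses the reference dose at each point", {
  ref <- planar_dose(matrix(c(100, 200, 400, 800), 2, 2), pitch = 50)
  ev <- planar_dose(matrix(c(103, 206, 412, 824), 2, 2), pitch = 50)
  r <- compute_gamma(ref, ev, gamma_criteria(norm = "local", threshold = 0),
                     radius_factor = 0.01)
  expect_equal(as.vector(r$gamma), rep(1, 4), tolerance = 1e-9)
})

test_that("volumetric gamma matches the oracle on a small random grid", {
  set.seed(77)
  mk <- function() dose_grid(array(100 + rnorm(6^3, 0, 4), c(6, 6, 6)),
                             c(4, 4, 4), c(0, 0, 0))
  ref <- mk(); ev <- mk()
  crit <- gamma_criteria(norm = "prescription", threshold = 0)
  fast <- compute_gamma(ref, ev, crit, norm_dose = 100, subsample = 4)
  slow <- gamma_oracle(ref, ev, crit, norm_dose = 100, subsample = 4)
  expect_lt(max(abs(fast$gamma - slow$gamma)), 1e-6)
})

test_that("prescription normalization requires a dose and rejects zero", {
  p <- planar_dose(matrix(100, 4, 4), pitch = 5)
  expect_error(compute_gamma(p, p, gamma_criteria(norm = "prescription")),
               "supply `norm_dose`")
  expect_error(compute_gamma(p, p, gamma_criteria(norm = "prescription"),
                             norm_dose = 0), "positive")
  z <- planar_dose(matrix(0, 4, 4), pitch = 5)
  expect_error(compute_gamma(z, z), "normalization dose is zero")
})
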