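test_that("phantom voxelisation covers the stated box", {
  g <- make_phantom()
  expect_equal(dim(g$values),
               c(ceiling(314 / 3), ceiling(340 / 3), ceiling(220 / 3)))
  expect_equal(g$spacing, c(3, 3, 3))
  g10 <- make_phantom(10)
  expect_equal(dim(g10$values), c(32, 34, 22))
  # centered on the origin, voxel-center convention
  ax <- grid_axes(g10)
  expect_equal(mean(range(ax$x)), 0)
  expect_error(make_phantom(-1), "positive")
})

test_that("NPC template nests its targets and is seed-deterministic", {
  g <- make_phantom(6)
  a <- make_npc_structures(g, seed = 4, jitter = 2)
  expect_true(all(c("PTVnx", "PTV1", "PTV2", "brainstem", "spinal_cord",
                    "parotid_l", "parotid_r", "optic_nerve_l",
                    "optic_nerve_r", "optic_chiasm") %in% names(a$masks)))
  expect_true(all(a$masks$PTV1[a$masks$PTVnx]))
  expect_true(all(a$masks$PTV2[a$masks$PTV1]))
  expect_true(sum(a$masks$PTVnx) < sum(a$masks$PTV1))

  b <- make_npc_structures(g, seed = 4, jitter = 2)
  expect_identical(a$masks, b$masks)
  c <- make_npc_structures(g, seed = 5, jitter = 2)
  expect_false(identical(a$masks, c$masks))
  expect_error(make_npc_structures(make_phantom(3, dims_cm = c(5, 5, 5))),
               "too small")
})

test_that("margin expansion grows the target by the analytic amount", {
  g <- make_phantom(3)
  ss <- make_npc_structures(g, margin1 = 5)
  vol <- function(semi) 4 / 3 * pi * prod(semi) / 1000
  expect_lt(abs(ss$volumes[["PTVnx"]] - vol(c(25, 20, 20))) /
              vol(c(25, 20, 20)), 0.05)
  expect_lt(abs(ss$volumes[["PTV1"]] - vol(c(30, 25, 25))) /
              vol(c(30, 25, 25)), 0.05)
})

test_that("the analytic plan saturates at prescription inside large targets", {
  g <- make_phantom(3)
  ss <- make_npc_structures(g)
  rx <- prescription(c(PTVnx = 7000, PTV1 = 6600, PTV2 = 6000))
  plan <- make_planned_dose(ss, rx, sigma = 4)
  center <- which(abs(grid_axes(g)$x - 0) < 1.6)[1]
  cy <- which(abs(grid_axes(g)$y - 10) < 1.6)[1]
  cz <- which(abs(grid_axes(g)$z - 10) < 1.6)[1]
  expect_lt(abs(plan$values[center, cy, cz] - 7000) / 7000, 0.001)
  # far from any target the dose vanishes
  expect_lt(plan$values[1, 1, 1], 1e-6)
  # a near-delta penumbra reduces to the indicator
  sharp <- make_planned_dose(ss, rx, sigma = 0.3)
  inside <- ss$masks$PTVnx
  expect_lt(max(abs(sharp$values[inside] - 7000)) / 7000, 0.001)
  expect_error(make_planned_dose(ss, prescription(c(nope = 100))),
               "no mask")
})

test_that("plan renormalization pins D95 of the boost target", {
  g <- make_phantom(6)
  ss <- make_npc_structures(g)
  rx <- prescription(c(PTVnx = 7000, PTV1 = 6600, PTV2 = 6000))
  plan <- make_planned_dose(ss, rx, sigma = 4, normalize = TRUE)
  d95 <- dose_at_volume(cumulative_dvh(plan, "PTVnx", ss), 0.95)
  expect_equal(d95, 7000, tolerance = 1e-9)
})

test_that("the identity perturbation is bitwise identity", {
  g <- make_phantom(10)
  co <- coord_arrays(g)
  dose <- dose_grid(exp(-(co$X^2 + co$Y^2 + co$Z^2) / 5000) * 100,
                    g$spacing, g$origin)
  out <- perturb_dose(dose, perturbation_spec())
  expect_identical(out$values, dose$values)
})

test_that("a pure scale shifts every DVH dose metric by the same factor", {
  rs <- ramp_sphere(spacing = 2)
  pert <- perturb_dose(rs$dose, perturbation_spec(scale = 1.02))
  cv0 <- cumulative_dvh(rs$dose, rs$mask)
  cv1 <- cumulative_dvh(pert, rs$mask)
  for (v in c(0.02, 0.5, 0.95, 0.98))
    expect_equal(relative_deviation(dose_at_volume(cv1, v),
                                    dose_at_volume(cv0, v)),
                 2, tolerance = 1e-12)
  expect_equal(relative_deviation(mean(cv1$doses), mean(cv0$doses)),
               2, tolerance = 1e-12)
})

test_that("perturbation noise is seeded and leaves the RNG state alone", {
  g <- make_phantom(10)
  dose <- dose_grid(array(100, dim(g$values)), g$spacing, g$origin)
  spec <- perturbation_spec(noise = 1, seed = 42)
  set.seed(123); before <- runif(1)
  a <- perturb_dose(dose, spec)
  b <- perturb_dose(dose, spec)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values,
                         perturb_dose(dose, perturbation_spec(noise = 1,
                                                              seed = 43))$values))
  set.seed(123)
  expect_identical(runif(1), before) # generators restore the RNG
})

test_that("rigid shift moves the distribution by the stated vector", {
  gp <- ramp_sphere(spacing = 2)
  sh <- perturb_dose(gp$dose, perturbation_spec(shift = c(4, 0, 0)))
  d <- dim(gp$dose$values)
  mid <- ceiling(d / 2)
  # ramp along x: D(x) moves by +4 mm = 2 voxels
  expect_equal(sh$values[5:(d[1] - 1), mid[2], mid[3]],
               gp$dose$values[3:(d[1] - 3), mid[2], mid[3]],
               tolerance = 1e-9)
})

test_that("detector sampling reproduces fields at lattice positions", {
  field <- planar_dose(matrix(77, 61, 61), pitch = 5,
                       origin = c(-150, -150))
  arr <- sample_detector_array(field)
  expect_equal(dim(arr$values), c(32, 32))
  expect_equal(sum(arr$active), 1020)
  expect_equal(arr$values[arr$active], rep(77, 1020), tolerance = 1e-12)
  expect_true(all(arr$values[!arr$active] == 0))

  # bilinear sampling of a linear ramp is exact
  x <- seq(-150, 150, by = 5)
  ramp <- planar_dose(matrix(rep(2 * x + 10, 61), 61, 61), pitch = 5,
                      origin = c(-150, -150))
  sr <- sample_detector_array(ramp)
  xs <- sr$origin[1] + (0:31) * 7.62
  expect_equal(sr$values[, 16], ifelse(sr$active[, 16], 2 * xs + 10, 0),
               tolerance = 1e-9)
  small <- planar_dose(matrix(1, 5, 5), pitch = 5)
  expect_error(sample_detector_array(small), "outside the planar field")
})

test_that("the response model dips at lateral incidence with unit normal", {
  m <- response_model(A = 0.2, w = 10, ripple = 0.005)
  expect_equal(response_at(m, 0), 1)
  raw0 <- 1 - 0.2 * (exp(-90^2 / 200) + exp(-270^2 / 200))
  expect_equal(response_at(m, 90), (1 - 0.2 - 0.005) / raw0, tolerance = 1e-9)
  expect_lt(response_at(m, 90), response_at(m, 45))
  expect_equal(response_at(m, 90), response_at(m, 270), tolerance = 1e-12)
  expect_error(response_model(A = 1.2), "\\[0, 1\\)")
  expect_error(response_model(A = 0.999, ripple = 0.5), "positive")
})
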