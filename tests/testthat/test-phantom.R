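test_that("plasma running integral matches closed forms and quadrature", {
  sch <- standard_schedule("16x150")
  ## constant input: integral is c0 * t exactly
  cp <- simulate_plasma_input(500, 0, sch)
  t <- c(1, 7.5, 33.3)
  expect_equal(plasma_integral(cp, t), 500 * t)
  ## single exponential against a dense trapezoid oracle
  cp <- simulate_plasma_input(200, 0.25, sch)
  g <- seq(0, 40, length.out = 200001)
  cg <- 200 * exp(-0.25 * g)
  trap <- sum(diff(g) * (cg[-1] + cg[-length(cg)]) / 2)
  expect_equal(plasma_integral(cp, 40), trap, tolerance = 1e-9)
  expect_equal(plasma_integral(cp, 40), (200 / 0.25) * (1 - exp(-0.25 * 40)))
  ## determinism
  expect_identical(simulate_plasma_input(c(2, 3), c(1, 0.1), sch),
                   simulate_plasma_input(c(2, 3), c(1, 0.1), sch))
})

test_that("plasma input rejects invalid parameter sets", {
  sch <- standard_schedule("8x300")
  expect_error(simulate_plasma_input(numeric(0), numeric(0), sch),
               "at least one")
  expect_error(simulate_plasma_input(c(5, -1), c(1, 1), sch), "negative")
})

test_that("noiseless phantom TACs are Patlak-linear by construction", {
  sch <- standard_schedule("16x150")
  cp <- simulate_plasma_input(c(800, 100, 60), c(4, 0.3, 0.01), sch)
  ki <- array(0.015, dim = c(3, 3, 3)); vb <- array(0.04, dim = c(3, 3, 3))
  truth <- kinetic_ground_truth(ki, vb)
  ser <- simulate_dynamic_series(truth, cp, sch, noise_sd = 0)
  tc <- tissue_curve(ser$frames[2, 2, 2, ], sch)
  pts <- patlak_transform(tc, cp)
  expect_equal(pts$y, 0.015 * pts$x + 0.04, tolerance = 1e-12)
  fit <- fit_patlak_slope(pts, parametric_settings(t_star = 15,
                                                   window_end = 100))
  expect_equal(fit$ki, 0.015, tolerance = 1e-6)
  expect_equal(fit$intercept, 0.04, tolerance = 1e-9)
})

test_that("constant plasma with vb = 0 gives a TAC linear in midpoint time", {
  sch <- standard_schedule("8x300")
  cp <- simulate_plasma_input(100, 0, sch)
  truth <- kinetic_ground_truth(array(0.02, c(2, 2, 2)),
                                array(0, c(2, 2, 2)))
  ser <- simulate_dynamic_series(truth, cp, sch, noise_sd = 0)
  expect_equal(ser$frames[1, 1, 1, ], 0.02 * 100 * frame_midpoints_min(sch),
               tolerance = 1e-12)
})

test_that("noise is seed-deterministic and seeds differ", {
  geom <- phantom_geometry(dims = c(10, 10, 8), radii = c(3.2, 2.6, 2.2))
  sch <- standard_schedule("16x150")
  cp <- simulate_plasma_input(c(800, 100, 60), c(4, 0.3, 0.01), sch)
  a <- simulate_dynamic_series(geom$truth, cp, sch, noise_sd = 0.1, seed = 7)
  b <- simulate_dynamic_series(geom$truth, cp, sch, noise_sd = 0.1, seed = 7)
  c <- simulate_dynamic_series(geom$truth, cp, sch, noise_sd = 0.1, seed = 8)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, c$frames))
  ## whole-phantom regeneration is bit-identical
  expect_identical(simulate_phantom(seed = 3, noise_sd = 0.05),
                   simulate_phantom(seed = 3, noise_sd = 0.05))
})

test_that("schedule beyond a sampled plasma curve's support is rejected", {
  sch <- standard_schedule("16x150")
  cp_short <- plasma_curve(c(1, 5, 20), c(50, 30, 10))
  truth <- kinetic_ground_truth(array(0.01, c(2, 2, 2)),
                                array(0, c(2, 2, 2)))
  expect_error(simulate_dynamic_series(truth, cp_short, sch), "support")
})

test_that("sum_frames halves the 16x150 schedule into 8x300", {
  ph <- simulate_phantom(seed = 2, noise_sd = 0.05)
  s300 <- sum_frames(ph$series, 2)
  expect_equal(n_frames(s300$schedule), 8)
  expect_equal(s300$schedule$durations, rep(300, 8))
  expect_equal(s300$schedule$starts, 600 + 300 * (0:7))
  ## duration-weighted mean of equal-duration pairs
  expect_equal(s300$frames[, , , 1],
               (ph$series$frames[, , , 1] + ph$series$frames[, , , 2]) / 2)
})

test_that("sum_frames respects identity and constant-series invariants", {
  ph <- simulate_phantom(seed = 4, noise_sd = 0)
  expect_identical(sum_frames(ph$series, 1), ph$series)
  ## constant series stays constant with the same value
  const <- dynamic_series(array(7, c(2, 2, 2, 4)),
                          frame_schedule(c(0, 60, 120, 180), rep(60, 4)))
  sc <- sum_frames(const, 2)
  expect_equal(as.vector(sc$frames), rep(7, 16))
  expect_error(sum_frames(ph$series, 3), "divisible")
})

test_that("derive_static_image is a duration-weighted frame mean", {
  fs <- frame_schedule(c(0, 100), c(100, 100))
  ser <- dynamic_series(array(rep(c(1, 3), each = 8), c(2, 2, 2, 2)), fs)
  img <- derive_static_image(ser, c(0, 200))
  expect_equal(as.vector(img$values), rep(2, 8))
  ## single-frame window returns that frame unchanged
  one <- derive_static_image(ser, c(0, 100))
  expect_equal(one$values, ser$frames[, , , 1])
  expect_error(derive_static_image(ser, c(0, 150)), "covered")
})

test_that("summing then averaging commutes with direct averaging", {
  ph <- simulate_phantom(seed = 5, noise_sd = 0.1)
  w <- c(600, 3000)
  a <- derive_static_image(ph$series, w)
  b <- derive_static_image(sum_frames(ph$series, 2), w)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("default phantom geometry has the promised structure", {
  geom <- phantom_geometry()
  expect_gte(sum(geom$mask$values), 500)
  ki_in <- geom$truth$ki_map[geom$mask$values]
  ki_out <- geom$truth$ki_map[!geom$mask$values]
  expect_gt(min(ki_in), max(ki_out))      # lesion hotter than background
  expect_gt(length(unique(ki_in)), 10)    # genuine Ki texture
})
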