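test_that("NIfTI round-trip preserves values, spacing and origin", {
  set.seed(11)
  img <- pet_image(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                   spacing = c(2.56, 2.56, 3.38), origin = c(-10, 4, 22),
                   units = "Bq/mL")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(img, f)
  back <- read_volume(f, "image", units = "Bq/mL")
  expect_equal(back$values, img$values, tolerance = 1e-6)
  expect_equal(back$spacing, img$spacing, tolerance = 1e-6)
  expect_equal(back$origin, img$origin, tolerance = 1e-5)
})

test_that("mask files must be strictly binary", {
  m <- array(0, c(3, 3, 3)); m[2, 2, 2] <- 1
  f <- tempfile(fileext = ".nii.gz")
  write_volume(voi_mask(m), f)
  expect_s3_class(read_volume(f, "mask"), "voi_mask")
  bad <- pet_image(array(c(rep(0, 25), 1, 2), c(3, 3, 3)))
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(bad, f2)
  expect_error(read_volume(f2, "mask"), "not binary")
})

test_that("4D NIfTI round-trips as a dynamic series", {
  ph <- simulate_phantom(seed = 9, noise_sd = 0.05)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(ph$series, f)
  fs <- tempfile(fileext = ".csv")
  write_schedule_csv(ph$schedule, fs)
  back <- read_dynamic_series(f, fs)
  expect_equal(dim(back$frames)[4], 16)
  expect_equal(back$frames, ph$series$frames, tolerance = 1e-6)
  expect_equal(back$schedule$starts, ph$schedule$starts)
})

test_that("resampling a constant image yields a constant image", {
  img <- pet_image(array(3.7, c(5, 6, 4)), spacing = c(2, 2, 3))
  out <- resample_isotropic(img, 1.5)
  expect_equal(as.vector(out$values), rep(3.7, prod(dim(out$values))))
  expect_equal(out$spacing, rep(1.5, 3))
})

test_that("trilinear resampling is exact on a world-linear field", {
  sp <- c(2.5, 2, 3); org <- c(5, -3, 1)
  d <- c(6, 7, 5)
  wx <- function(i, ax) org[ax] + (i - 1) * sp[ax]
  vol <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    vol[i, j, k] <- 2 * wx(i, 1) - 0.5 * wx(j, 2) + 0.25 * wx(k, 3)
  img <- pet_image(vol, sp, org)
  out <- resample_isotropic(img, 1.7)
  do <- dim(out$values)
  ## interior output samples (inside the input support, where no edge
  ## clamping occurs) must reproduce the linear field exactly
  for (i in 3:(do[1] - 2)) for (j in 3:(do[2] - 2)) for (k in 3:(do[3] - 2)) {
    w <- out$origin + (c(i, j, k) - 1) * 1.7
    expect_equal(out$values[i, j, k], 2 * w[1] - 0.5 * w[2] + 0.25 * w[3],
                 tolerance = 1e-9)
  }
})

test_that("resampled grid is centre-aligned and covers the input extent", {
  img <- pet_image(array(1, c(10, 8, 6)), spacing = c(2.56, 2.56, 3.38),
                   origin = c(3, -7, 12))
  out <- resample_isotropic(img, 3.38)
  cin <- img$origin + (dim(img$values) - 1) / 2 * img$spacing
  cout <- out$origin + (dim(out$values) - 1) / 2 * out$spacing
  expect_equal(cin, cout, tolerance = 1e-12)
  expect_true(all(dim(out$values) * 3.38 >=
                    dim(img$values) * img$spacing - 1e-9))
})

test_that("resampling matches the direct 8-corner oracle voxel by voxel", {
  set.seed(21)
  for (rep in 1:3) {
    sp <- runif(3, 1.5, 3.5); org <- runif(3, -10, 10)
    vol <- array(runif(125), c(5, 5, 5))
    img <- pet_image(vol, sp, org)
    target <- runif(1, 0.8, 2)
    out <- resample_isotropic(img, target)
    do <- dim(out$values)
    sub <- expand.grid(i = seq(1, do[1], by = 2), j = seq(1, do[2], by = 2),
                       k = seq(1, do[3], by = 2))
    for (q in seq_len(nrow(sub))) {
      v <- as.numeric(sub[q, ])
      w <- out$origin + (v - 1) * target
      ci <- (w - org) / sp + 1
      expect_equal(out$values[v[1], v[2], v[3]],
                   oracle_trilinear_at(vol, ci), tolerance = 1e-12)
    }
  }
})

test_that("mean intensity of a smooth image survives resampling within 1%", {
  d <- c(20, 20, 16)
  vol <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    vol[i, j, k] <- 10 + sin(i / 6) + cos(j / 5) + k / 20
  img <- pet_image(vol, c(2, 2, 3))
  out <- resample_isotropic(img, 2.4)
  expect_lt(abs(mean(out$values) - mean(vol)) / mean(vol), 0.01)
})

test_that("mask resampling follows interpolate-then-threshold semantics", {
  ## full mask stays full at any spacing
  full <- voi_mask(array(TRUE, c(4, 4, 4)), spacing = c(2, 2, 2))
  out <- resample_mask(full, 1.3)
  expect_true(all(out$values))
  ## single voxel upsampled: blob contains the original centre (target
  ## chosen so an output sample lands on the voxel centre)
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  single <- voi_mask(m, spacing = c(2, 2, 2))
  up <- resample_mask(single, 10 / 7)
  centre_world <- single$origin + 2 * single$spacing
  ci <- round((centre_world - up$origin) / up$spacing) + 1
  expect_true(up$values[ci[1], ci[2], ci[3]])
  ## random blob equals the brute-force interpolate-then-threshold oracle
  set.seed(31)
  blob <- array(runif(6 * 5 * 4) < 0.5, c(6, 5, 4))
  blob[3, 3, 2] <- TRUE
  bm <- voi_mask(blob, spacing = c(2.5, 2, 3))
  rs <- resample_mask(bm, 1.6)
  do <- dim(rs$values)
  field <- array(as.numeric(blob), dim(blob))
  for (q in 1:60) {
    v <- c(sample(do[1], 1), sample(do[2], 1), sample(do[3], 1))
    w <- rs$origin + (v - 1) * 1.6
    ci <- (w - bm$origin) / bm$spacing + 1
    expect_identical(rs$values[v[1], v[2], v[3]],
                     oracle_trilinear_at(field, ci) >= 0.5)
  }
})

test_that("series resampling is frame-independent", {
  ph <- simulate_phantom(seed = 12, noise_sd = 0.1,
                         geometry = phantom_geometry(dims = c(10, 10, 8),
                                                     radii = c(3.2, 2.7,
                                                               2.2)))
  rs <- resample_series(ph$series, 2.5)
  for (t in c(1, 8, 16)) {
    single <- resample_isotropic(get_frame(ph$series, t), 2.5)
    expect_equal(rs$frames[, , , t], single$values, tolerance = 1e-12)
  }
})

test_that("extract_voi_values is deterministic lexicographic order", {
  vol <- array(seq_len(27), c(3, 3, 3))
  m <- array(FALSE, c(3, 3, 3)); m[2, 1, 1] <- TRUE; m[1, 3, 2] <- TRUE
  got <- extract_voi_values(pet_image(vol), voi_mask(m))
  expect_equal(got$value, c(2, 16))     # column-major order: (2,1,1), (1,3,2)
  expect_equal(got$i, c(2, 1))
  full <- extract_voi_values(pet_image(vol), voi_mask(array(TRUE, c(3, 3, 3))))
  expect_equal(full$value, as.vector(vol))
  expect_error(extract_voi_values(pet_image(vol),
                                  voi_mask(array(TRUE, c(2, 2, 2)))),
               "grids differ")
  expect_error(resample_isotropic(pet_image(array(1:4, c(1, 2, 2))), 0.5),
               "degenerate")
})
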