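test_that("the 13 neighbour directions cover the 26-neighbourhood", {
  dirs <- neighbour_directions_3d()
  expect_equal(nrow(dirs), 13)
  expect_true(all(abs(dirs) <= 1))
  expect_true(all(rowSums(abs(dirs)) > 0))
  both <- rbind(dirs, -dirs)
  expect_equal(nrow(unique(both)), 26)
  ## no direction is the negation of another
  key <- apply(dirs, 1, paste, collapse = ",")
  negkey <- apply(-dirs, 1, paste, collapse = ",")
  expect_length(intersect(key, negkey), 0)
})

test_that("GLCM of a constant VOI is a single diagonal entry", {
  cv <- cuboid_voi(c(3, 3, 3), level = 2L)
  g <- build_glcm_3d(cv$levels, cv$mask)
  expect_equal(dim(g$counts), c(2, 2))
  expect_true(all(g$counts[-4] == 0))
  f <- glcm_features(g)
  expect_equal(unname(f["MaximumProbability"]), 1)
  expect_equal(unname(f["Contrast"]), 0)
})

test_that("GLCM matches the pair-enumeration oracle and is symmetric", {
  ## tiny worked example: 2x2x1 plane with levels [[1,2],[2,1]]
  m <- array(TRUE, c(2, 2, 1))
  lv <- array(c(1L, 2L, 2L, 1L), c(2, 2, 1))
  g <- build_glcm_3d(lv[which(m)], voi_mask(m))
  expect_equal(g$counts, oracle_glcm(lv, 2))
  ## random VOIs, entry-for-entry against the brute-force oracle
  set.seed(41)
  for (rep in 1:10) {
    v <- random_voi()
    g <- build_glcm_3d(v$levels, v$mask, ng = v$ng)
    expect_equal(g$counts, oracle_glcm(v$arr, v$ng))
    expect_equal(g$counts, t(g$counts))
  }
})

test_that("GLRLM, GLSZM and NGTDM match their brute-force oracles", {
  ## 1x1xL line: one run of length L
  line <- cuboid_voi(c(1, 1, 4))
  r <- build_glrlm_3d(line$levels, line$mask)
  expect_equal(r$counts[1, 4], 1)    # the axis-aligned full-length run
  ## constant VOI: a single zone of size n
  cv <- cuboid_voi(c(3, 2, 2))
  z <- build_glszm(cv$levels, cv$mask)
  expect_equal(sum(z$counts), 1)
  expect_equal(z$counts[1, 12], 1)
  set.seed(42)
  for (rep in 1:10) {
    v <- random_voi()
    expect_equal(build_glrlm_3d(v$levels, v$mask, ng = v$ng)$counts,
                 oracle_glrlm(v$arr, v$ng))
    expect_equal(build_glszm(v$levels, v$mask, ng = v$ng)$counts,
                 oracle_glszm(v$arr, v$ng))
    got <- build_ngtdm(v$levels, v$mask, ng = v$ng)
    want <- oracle_ngtdm(v$arr, v$ng)
    expect_equal(got$n_i, want$n_i)
    expect_equal(got$s_i, want$s_i, tolerance = 1e-12)
    expect_equal(got$n_vp, want$n_vp)
  }
})

test_that("matrix conservation laws hold", {
  set.seed(43)
  for (rep in 1:5) {
    v <- random_voi()
    nvox <- sum(v$mask$values)
    r <- build_glrlm_3d(v$levels, v$mask, ng = v$ng)
    jmat <- matrix(seq_len(ncol(r$counts)), nrow(r$counts), ncol(r$counts),
                   byrow = TRUE)
    expect_equal(sum(r$counts * jmat), nvox * 13)
    z <- build_glszm(v$levels, v$mask, ng = v$ng)
    smat <- matrix(seq_len(ncol(z$counts)), nrow(z$counts), ncol(z$counts),
                   byrow = TRUE)
    expect_equal(sum(z$counts * smat), nvox)
    g <- build_glcm_3d(v$levels, v$mask, ng = v$ng)
    expect_equal(sum(g$counts / sum(g$counts)), 1)
  }
})

test_that("hand-computed GLCM features on a known probability matrix", {
  ## P = [[0, .5], [.5, 0]]: Contrast = 1, JointEnergy = 0.5
  f <- glcm_features(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(unname(f["Contrast"]), 1)
  expect_equal(unname(f["JointEnergy"]), 0.5)
  expect_equal(unname(f["Correlation"]), -1)
  expect_equal(unname(f["MaximumProbability"]), 0.5)
  expect_equal(unname(f["JointEntropy"]), 1)
})

test_that("degenerate single-level matrices follow documented conventions", {
  cv <- cuboid_voi(c(3, 3, 2))
  f <- glcm_features(build_glcm_3d(cv$levels, cv$mask))
  expect_equal(unname(f["Correlation"]), 1)
  expect_equal(unname(f["Imc1"]), 0)
  expect_equal(unname(f["Imc2"]), 0)
  expect_equal(unname(f["InverseVariance"]), 0)   # i = j terms omitted
  expect_false(any(is.na(f)))
  n <- ngtdm_features(build_ngtdm(cv$levels, cv$mask))
  expect_equal(unname(n[c("Contrast", "Busyness", "Strength")]), c(0, 0, 0))
})

test_that("GLRLM features: run percentage accounts for 13 directions", {
  cv <- cuboid_voi(c(4, 4, 4))
  r <- build_glrlm_3d(cv$levels, cv$mask)
  f <- glrlm_features(r)
  ## coverage = 64 voxels x 13 directions; oracle recomputation
  want <- oracle_glrlm(cv$arr, 1)
  nr <- sum(want)
  expect_equal(unname(f["RunPercentage"]), nr / (64 * 13))
  expect_equal(unname(f["GrayLevelNonUniformity"]), nr)
})

test_that("full static extraction returns the 90-feature contract", {
  ph <- simulate_phantom(seed = 14, noise_sd = 0.05)
  fs <- extract_static_feature_set(ph$static, ph$mask, 5)
  expect_equal(nrow(fs), 90)
  counts <- table(fs$family)
  expect_equal(as.vector(counts[c("intensity", "shape", "glcm", "glrlm",
                               "glszm", "ngtdm")]),
               c(18L, 13L, 22L, 16L, 16L, 5L))
  expect_false(any(duplicated(paste(fs$family, fs$feature))))
  expect_true(all(is.finite(fs$value)))
  ## identical call twice gives identical output
  expect_identical(fs, extract_static_feature_set(ph$static, ph$mask, 5))
})

test_that("texture features are invariant to intensity/width rescaling", {
  ph <- simulate_phantom(seed = 15, noise_sd = 0.05)
  f1 <- extract_static_feature_set(ph$static, ph$mask, 4)
  img2 <- pet_image(ph$static$values * 7, ph$static$spacing,
                    ph$static$origin, ph$static$units)
  f2 <- extract_static_feature_set(img2, ph$mask, 28)
  tex <- f1$family %in% c("glcm", "glrlm", "glszm", "ngtdm")
  expect_equal(f2$value[tex], f1$value[tex], tolerance = 1e-12)
})

test_that("merged-matrix texture features are rotation invariant", {
  set.seed(44)
  v <- random_voi(max_dim = 6, ng = 3)
  rot_arr <- rot90_z(v$arr)
  rot_mask <- voi_mask(rot90_z(array(v$mask$values, dim(v$mask$values))))
  for (build in list(build_glcm_3d, build_glrlm_3d, build_glszm)) {
    a <- build(v$levels, v$mask, ng = v$ng)$counts
    b <- build(rot_arr[which(rot_mask$values)], rot_mask, ng = v$ng)$counts
    expect_equal(a, b)
  }
  n1 <- build_ngtdm(v$levels, v$mask, ng = v$ng)
  n2 <- build_ngtdm(rot_arr[which(rot_mask$values)], rot_mask, ng = v$ng)
  expect_equal(n1$n_i, n2$n_i)
  expect_equal(n1$s_i, n2$s_i, tolerance = 1e-12)
})

test_that("structured lesions show higher GLCM contrast than uniform ones", {
  geom_hot <- phantom_geometry()
  geom_flat <- phantom_geometry(ki_focal = 0.03, ki_lesion = 0.03,
                                ki_background = 0.002)
  ## flatten the in-lesion gradient for the homogeneous comparator
  geom_flat$truth$ki_map[geom_flat$mask$values] <- 0.03
  sch <- standard_schedule("16x150")
  cp <- simulate_plasma_input(c(800, 100, 60), c(4, 0.3, 0.01), sch)
  mk_static <- function(geom) {
    ser <- simulate_dynamic_series(geom$truth, cp, frame_schedule(3000, 600),
                                   noise_sd = 0)
    derive_static_image(ser, c(3000, 3600))
  }
  f_hot <- extract_static_feature_set(mk_static(geom_hot), geom_hot$mask, 100)
  f_flat <- extract_static_feature_set(mk_static(geom_flat), geom_flat$mask,
                                       100)
  pick <- function(f) f$value[f$family == "glcm" & f$feature == "Contrast"]
  expect_gt(pick(f_hot), pick(f_flat))
})

test_that("shape features are geometrically sensible on known solids", {
  ## digital ball: mesh volume within a few percent of the analytic volume,
  ## sphericity near 1, diameters near 2r
  d <- c(21, 21, 21); ctr <- c(11, 11, 11); r <- 8
  m <- array(FALSE, d)
  for (i in 1:21) for (j in 1:21) for (k in 1:21)
    m[i, j, k] <- sum((c(i, j, k) - ctr)^2) <= r^2
  ball <- voi_mask(m, spacing = c(1, 1, 1))
  f <- shape_features(ball)
  expect_equal(unname(f["MeshVolume"]), 4 / 3 * pi * r^3, tolerance = 0.05)
  expect_gt(unname(f["Sphericity"]), 0.9)
  expect_lte(unname(f["Sphericity"]), 1.05)
  expect_equal(unname(f["Maximum3DDiameter"]), 2 * r, tolerance = 0.1)
  expect_equal(unname(f["Elongation"]), 1, tolerance = 0.05)
  expect_equal(unname(f["Flatness"]), 1, tolerance = 0.05)
  ## axis-aligned box: exact voxel-boundary volume is (n - [0.5 shell]) --
  ## mesh at the 0.5 level sits half a voxel outside the outer voxel centres
  box <- voi_mask(array(TRUE, c(4, 3, 2)), spacing = c(2, 2, 2))
  fb <- shape_features(box)
  expect_gt(unname(fb["MeshVolume"]), 0)
  expect_gt(unname(fb["SurfaceArea"]), 0)
  expect_lt(unname(fb["Sphericity"]), 1)
  ## anisotropic ellipsoid is elongated and flat
  fe <- shape_features(phantom_geometry()$mask)
  expect_lt(unname(fe["Elongation"]), 1)
  expect_lt(unname(fe["Flatness"]), unname(fe["Elongation"]))
})

test_that("intensity features match direct formulas", {
  set.seed(45)
  x <- rlnorm(500)
  lv <- apply_fixed_width(x, 0.25)$levels
  f <- intensity_features(x, lv, voxel_volume_mm3 = 3.38^3)
  expect_equal(unname(f["Mean"]), mean(x))
  expect_equal(unname(f["Variance"]), mean((x - mean(x))^2))
  expect_equal(unname(f["Energy"]), sum(x^2))
  expect_equal(unname(f["TotalEnergy"]), 3.38^3 * sum(x^2))
  expect_equal(unname(f["RootMeanSquared"]), sqrt(mean(x^2)))
  expect_equal(unname(f["Range"]), max(x) - min(x))
  p <- tabulate(lv) / length(lv); p <- p[p > 0]
  expect_equal(unname(f["Entropy"]), -sum(p * log2(p)))
  expect_equal(unname(f["Uniformity"]), sum(p^2))
  ## constant input: entropy 0, zero-variance conventions
  fc <- intensity_features(rep(2, 20), rep(1L, 20))
  expect_equal(unname(fc[c("Entropy", "Variance", "Skewness", "Kurtosis")]),
               c(0, 0, 0, 0))
})
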