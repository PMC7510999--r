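## ---- grey level co-occurrence features -------------------------------------
## All formulas are written for a general (possibly asymmetric) matrix: row
## and column marginals are kept separate, so the same code serves the
## symmetric spatial GLCM and the causal temporal GLCM. For a symmetric
## matrix the expressions reduce to the usual definitions.

log2p <- function(p) ifelse(p > 0, log2(p), 0)

#' Co-occurrence (GLCM) feature family
#'
#' The 22 co-occurrence features computed from a normalised Ng x Ng matrix.
#' Degenerate conventions for a single-cell matrix (e.g. a constant VOI):
#' Correlation = 1, IMC1 = 0, IMC2 = 0; InverseVariance always omits the
#' diagonal. These conventions keep outputs deterministic instead of NaN.
#'
#' @param glcm a `cooccurrence_matrix` (or bare count matrix).
#' @return named numeric vector of 22 features.
#' @export
glcm_features <- function(glcm) {
  C <- if (inherits(glcm, "cooccurrence_matrix")) glcm$counts else
    as.matrix(glcm)
  ng <- nrow(C)
  P <- C / sum(C)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  ## diagonal-band (difference) and anti-diagonal (sum) distributions
  kd <- 0:(ng - 1)
  pdiff <- vapply(kd, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * ng)
  psum <- vapply(ks, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(kd * pdiff)
  hxy <- -sum(P * log2p(P))
  pipj <- outer(px, py)
  hxy1 <- -sum(P * log2p(pipj))
  hxy2 <- -sum(pipj * log2p(pipj))
  hx <- -sum(px * log2p(px)); hy <- -sum(py * log2p(py))
  corr <- if (sx * sy < .Machine$double.eps) 1 else
    (sum(i * j * P) - mux * muy) / (sx * sy)
  imc1 <- if (max(hx, hy) < .Machine$double.eps) 0 else
    (hxy - hxy1) / max(hx, hy)
  imc2 <- sqrt(1 - exp(-2 * max(hxy2 - hxy, 0)))
  off <- i != j
  c(
    Autocorrelation     = sum(i * j * P),
    ClusterProminence   = sum((i + j - mux - muy)^4 * P),
    ClusterShade        = sum((i + j - mux - muy)^3 * P),
    ClusterTendency     = sum((i + j - mux - muy)^2 * P),
    Contrast            = sum((i - j)^2 * P),
    Correlation         = corr,
    DifferenceAverage   = da,
    DifferenceEntropy   = -sum(pdiff * log2p(pdiff)),
    DifferenceVariance  = sum((kd - da)^2 * pdiff),
    Id                  = sum(P / (1 + abs(i - j))),
    Idm                 = sum(P / (1 + (i - j)^2)),
    Idmn                = sum(P / (1 + (i - j)^2 / ng^2)),
    Idn                 = sum(P / (1 + abs(i - j) / ng)),
    Imc1                = imc1,
    Imc2                = imc2,
    InverseVariance     = sum(P[off] / (i[off] - j[off])^2),
    JointAverage        = mux,
    JointEnergy         = sum(P^2),
    JointEntropy        = hxy,
    MaximumProbability  = max(P),
    SumEntropy          = -sum(psum * log2p(psum)),
    SumSquares          = sum((i - mux)^2 * P)
  )
}

## ---- run length / size zone features ---------------------------------------
## GLRLM and GLSZM share one formula family over an Ng x M count matrix; only
## the normaliser of the "percentage" feature differs (runs cover each voxel
## once per direction, zones exactly once).

rl_family <- function(counts, names_prefix = c("Run", "Zone")) {
  kind <- match.arg(names_prefix)
  R <- counts
  ng <- nrow(R); lm <- ncol(R)
  nr <- sum(R)
  p <- R / nr
  i <- matrix(seq_len(ng), ng, lm)
  j <- matrix(seq_len(lm), ng, lm, byrow = TRUE)
  coverage <- sum(R * j)          # total voxel coverage (Nvox x Ndirections)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  short <- sum(p / j^2); long <- sum(p * j^2)
  out <- c(
    sum(p / j^2), sum(p * j^2),
    sum(rowSums(R)^2) / nr, sum(rowSums(R)^2) / nr^2,
    sum(colSums(R)^2) / nr, sum(colSums(R)^2) / nr^2,
    nr / coverage,
    sum(p * (i - mu_i)^2), sum(p * (j - mu_j)^2),
    -sum(p * log2p(p)),
    sum(p / i^2), sum(p * i^2),
    sum(p / (i^2 * j^2)), sum(p * i^2 / j^2),
    sum(p * j^2 / i^2), sum(p * i^2 * j^2)
  )
  nm <- if (kind == "Run") c(
    "ShortRunEmphasis", "LongRunEmphasis",
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
    "RunPercentage", "GrayLevelVariance", "RunVariance", "RunEntropy",
    "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
    "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
    "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"
  ) else c(
    "SmallAreaEmphasis", "LargeAreaEmphasis",
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
    "ZonePercentage", "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
    "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
    "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
    "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"
  )
  names(out) <- nm
  out
}

#' Run length (GLRLM) feature family
#'
#' 16 features from a run length matrix. RunPercentage is normalised by the
#' total voxel coverage `sum(counts * length)` (VOI voxels x directions for
#' the merged spatial matrix, VOI voxels x T for the temporal matrix).
#'
#' @param rlm a `runlength_matrix` (or bare count matrix).
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(rlm) {
  C <- if (inherits(rlm, "runlength_matrix")) rlm$counts else as.matrix(rlm)
  rl_family(C, "Run")
}

#' Size zone (GLSZM) feature family
#' @param szm a `sizezone_matrix` (or bare count matrix).
#' @return named numeric vector of 16 features.
#' @export
glszm_features <- function(szm) {
  C <- if (inherits(szm, "sizezone_matrix")) szm$counts else as.matrix(szm)
  rl_family(C, "Zone")
}

#' Neighbouring grey tone difference (NGTDM) feature family
#'
#' Coarseness, Contrast, Busyness, Complexity, Strength. Degenerate inputs
#' (a single occupied level) give Contrast = Busyness = Strength = 0;
#' Coarseness is capped at 1e6 when its denominator vanishes.
#'
#' @param ngtdm an `ngtdm_matrix` from [build_ngtdm()].
#' @return named numeric vector of 5 features.
#' @export
ngtdm_features <- function(ngtdm) {
  stopifnot(inherits(ngtdm, "ngtdm_matrix"))
  nvp <- ngtdm$n_vp
  occ <- which(ngtdm$n_i > 0)
  p <- ngtdm$n_i / nvp
  s <- ngtdm$s_i
  ngp <- length(occ)
  ps <- sum(p * s)
  coarseness <- if (ps < 1e-12) 1e6 else min(1 / ps, 1e6)
  if (ngp > 1) {
    pi_ <- p[occ]; si <- s[occ]; gi <- occ
    dif2 <- outer(gi, gi, function(a, b) (a - b)^2)
    contrast <- sum(outer(pi_, pi_) * dif2) / (ngp * (ngp - 1)) * sum(si) / nvp
    busy_den <- sum(abs(outer(gi * pi_, gi * pi_, `-`)))
    busyness <- if (busy_den < 1e-12) 0 else ps / busy_den
    complexity <- sum(abs(outer(gi, gi, `-`)) *
                        (outer(pi_ * si, pi_ * si, `+`)) /
                        outer(pi_, pi_, `+`)) / nvp
    strength <- if (sum(si) < 1e-12) 0 else
      sum(outer(pi_, pi_, `+`) * dif2) / sum(si)
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

## ---- first-order intensity features ----------------------------------------

#' Intensity (first-order) feature family
#'
#' 18 first-order features. All are computed on the raw (continuous) VOI
#' intensities except Entropy and Uniformity, which use the discretised
#' grey-level histogram. Skewness and Kurtosis are population moments
#' (Kurtosis is not excess-corrected); both are 0 for a constant VOI.
#'
#' @param values numeric VOI intensities.
#' @param levels integer discretised grey levels (same voxels).
#' @param voxel_volume_mm3 voxel volume, used by TotalEnergy.
#' @return named numeric vector of 18 features.
#' @export
intensity_features <- function(values, levels, voxel_volume_mm3 = 1) {
  n <- length(values)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  p10 <- unname(stats::quantile(values, 0.10))
  p90 <- unname(stats::quantile(values, 0.90))
  robust <- values[values >= p10 & values <= p90]
  hist_p <- tabulate(levels) / n
  hist_p <- hist_p[hist_p > 0]
  skew <- if (m2 < .Machine$double.eps) 0 else mean((values - m)^3) / m2^1.5
  kurt <- if (m2 < .Machine$double.eps) 0 else mean((values - m)^4) / m2^2
  c(
    Energy = sum(values^2),
    TotalEnergy = voxel_volume_mm3 * sum(values^2),
    Entropy = -sum(hist_p * log2(hist_p)),
    Minimum = min(values),
    Percentile10 = p10,
    Percentile90 = p90,
    Maximum = max(values),
    Mean = m,
    Median = unname(stats::median(values)),
    InterquartileRange = unname(stats::IQR(values, type = 7)),
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - m)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(hist_p^2)
  )
}

## ---- shape features --------------------------------------------------------

## Closed triangulated surface of a binary mask at the 0.5 iso-level, built
## by marching tetrahedra on the trilinearly interpolated partial-volume
## field: the mask is resampled to a finer grid (factor `upsample`), the
## zero-padded grid is split into cubes and each cube into six tetrahedra
## sharing the main diagonal; mixed tetrahedra contribute 1 or 2 triangles
## whose vertices sit at the linear 0.5-crossing of each edge. Adjacent
## cubes share face diagonals under this decomposition, so the mesh is
## crack-free; triangles are oriented outwards via the inside vertices.
## Upsampling smooths the binary staircase towards the trilinear isosurface
## (factor 2 is accurate to a few percent in surface area on digital balls).
mask_surface_mesh <- function(mask, upsample = 2L) {
  stopifnot(inherits(mask, "voi_mask"))
  d <- dim(mask$values)
  f <- array(as.numeric(mask$values), d)
  sp <- mask$spacing
  org <- mask$origin
  if (upsample > 1L) {
    tsp <- sp / upsample
    nd <- d * upsample
    torg <- org - (sp - tsp) / 2
    f <- trilinear_resample_array(f, sp, org, nd, tsp, torg)
    sp <- tsp; org <- torg; d <- nd
  }
  P <- array(0, d + 2L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- f
  ## padded voxel (i,j,k) centre sits at org + (i - 2) * sp in world space
  corner_off <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                      c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  tets <- rbind(c(1,2,3,7), c(1,3,4,7), c(1,4,8,7),
                c(1,8,5,7), c(1,5,6,7), c(1,6,2,7))
  dp <- dim(P)
  ## prefilter: only cubes with corners on both sides of 0.5 carry surface
  cs <- array(0L, dp - 1L)
  for (r in seq_len(8)) {
    o <- corner_off[r, ]
    cs <- cs + (P[(1 + o[1]):(dp[1] - 1 + o[1]),
                  (1 + o[2]):(dp[2] - 1 + o[2]),
                  (1 + o[3]):(dp[3] - 1 + o[3]), drop = FALSE] >= 0.5)
  }
  mixed <- which(cs > 0L & cs < 8L)
  if (length(mixed) == 0L)
    return(list(v1 = matrix(0, 0, 3), v2 = matrix(0, 0, 3),
                v3 = matrix(0, 0, 3)))
  ci <- arrayInd(mixed, dp - 1L)
  n1 <- dp[1]; n12 <- dp[1] * dp[2]
  ## corner values per mixed cell (vectorised gather)
  V <- matrix(0, length(mixed), 8)
  for (r in 1:8) {
    o <- corner_off[r, ]
    V[, r] <- P[(ci[, 1] + o[1]) + (ci[, 2] + o[2] - 1L) * n1 +
                  (ci[, 3] + o[3] - 1L) * n12]
  }
  B <- sweep(sweep(ci - 2, 2, sp, `*`), 2, org, `+`)  # corner-1 world pos
  cpos <- function(rows, loc)  # world position of local tet corner
    B[rows, , drop = FALSE] +
      matrix(corner_off[loc, ] * sp, length(rows), 3, byrow = TRUE)
  T1 <- list(); T2 <- list(); T3 <- list(); nt <- 0L
  emit <- function(p1, p2, p3, ref) {
    ## orient outwards: flip triangles whose normal points at the inside
    nrm <- rcross(p2 - p1, p3 - p1)
    flip <- rowSums(nrm * ((p1 + p2 + p3) / 3 - ref)) < 0
    tmp <- p2[flip, , drop = FALSE]
    p2[flip, ] <- p3[flip, , drop = FALSE]
    p3[flip, ] <- tmp
    nt <<- nt + 1L
    T1[[nt]] <<- p1; T2[[nt]] <<- p2; T3[[nt]] <<- p3
  }
  bits <- c(1L, 2L, 4L, 8L)
  for (s in 1:6) {
    tv <- tets[s, ]
    Vt <- V[, tv, drop = FALSE]
    caseid <- as.integer((Vt >= 0.5) %*% bits)
    for (cid in 1:14) {
      rows <- which(caseid == cid)
      if (length(rows) == 0L) next
      insl <- which(bitwAnd(cid, bits) > 0L)
      outl <- setdiff(1:4, insl)
      ## linear 0.5-crossing on local edge inside a -> outside b
      cp <- function(a, b) {
        va <- Vt[rows, a]; vb <- Vt[rows, b]
        pa <- cpos(rows, tv[a]); pb <- cpos(rows, tv[b])
        pa + ((va - 0.5) / (va - vb)) * (pb - pa)
      }
      ref <- Reduce(`+`, lapply(insl, function(a) cpos(rows, tv[a]))) /
        length(insl)
      if (length(insl) == 1L) {
        emit(cp(insl, outl[1]), cp(insl, outl[2]), cp(insl, outl[3]), ref)
      } else if (length(insl) == 3L) {
        emit(cp(insl[1], outl), cp(insl[2], outl), cp(insl[3], outl), ref)
      } else {
        q1 <- cp(insl[1], outl[1]); q2 <- cp(insl[1], outl[2])
        q3 <- cp(insl[2], outl[2]); q4 <- cp(insl[2], outl[1])
        emit(q1, q2, q3, ref)
        emit(q1, q3, q4, ref)
      }
    }
  }
  list(v1 = do.call(rbind, T1), v2 = do.call(rbind, T2),
       v3 = do.call(rbind, T3))
}

## row-wise cross product of n x 3 matrices
rcross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

## chunked maximum pairwise distance with optional coordinate projection
max_pairwise_dist <- function(pts, drop_axis = 0L) {
  if (drop_axis > 0L) pts <- pts[, -drop_axis, drop = FALSE]
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 2L) return(0)
  best <- 0
  chunk <- 256L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(pts^2), `+`) -
      2 * block %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Shape feature family
#'
#' 13 morphological features from the triangulated surface mesh of the mask
#' (marching tetrahedra at the 0.5 level) and the physical voxel-centre
#' point cloud: MeshVolume (divergence theorem), SurfaceArea,
#' SurfaceVolumeRatio, Sphericity, Maximum3DDiameter, the three maximum 2D
#' diameters (Slice/axial = dropping z, Column/coronal = dropping y,
#' Row/sagittal = dropping x), the three principal axis lengths
#' (4*sqrt(eigenvalue) of the coordinate covariance), Elongation and
#' Flatness. Units: mm and mm^3.
#'
#' @param mask a [voi_mask()].
#' @return named numeric vector of 13 features.
#' @export
shape_features <- function(mask) {
  mesh <- mask_surface_mesh(mask)
  a <- mesh$v1; b <- mesh$v2; c <- mesh$v3
  vol <- abs(sum(rowSums(a * rcross(b, c))) / 6)
  area <- sum(sqrt(rowSums(rcross(b - a, c - a)^2))) / 2
  verts <- unique(round(rbind(a, b, c), 9))
  sph <- (36 * pi * vol^2)^(1 / 3) / area
  ## principal axes from physical voxel-centre coordinates
  co <- arrayInd(which(mask$values), dim(mask$values))
  phys <- sweep(sweep(co - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
  ev <- if (nrow(phys) > 1)
    sort(pmax(eigen(stats::cov(phys) * (nrow(phys) - 1) / nrow(phys),
                    symmetric = TRUE, only.values = TRUE)$values, 0),
         decreasing = TRUE)
  else c(0, 0, 0)
  c(
    MeshVolume = vol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = sph,
    Maximum3DDiameter = max_pairwise_dist(verts),
    Maximum2DDiameterSlice = max_pairwise_dist(verts, drop_axis = 3L),
    Maximum2DDiameterColumn = max_pairwise_dist(verts, drop_axis = 2L),
    Maximum2DDiameterRow = max_pairwise_dist(verts, drop_axis = 1L),
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  )
}

## ---- family dispatcher and full extraction ---------------------------------

#' Compute one feature family
#'
#' Thin dispatcher over the family-specific functions; returns a tidy
#' fragment of (family, feature, value) rows.
#'
#' @param x family-appropriate input: a matrix object for the texture
#'   families, `list(values=, levels=, voxel_volume_mm3=)` for intensity, a
#'   [voi_mask()] for shape.
#' @param family one of `"intensity"`, `"shape"`, `"glcm"`, `"glrlm"`,
#'   `"glszm"`, `"ngtdm"`.
#' @return data.frame with columns family, feature, value.
#' @export
compute_family_features <- function(x, family = c("intensity", "shape",
                                                  "glcm", "glrlm", "glszm",
                                                  "ngtdm")) {
  family <- match.arg(family)
  v <- switch(family,
    intensity = intensity_features(x$values, x$levels,
                                   x$voxel_volume_mm3 %||% 1),
    shape = shape_features(x),
    glcm = glcm_features(x),
    glrlm = glrlm_features(x),
    glszm = glszm_features(x),
    ngtdm = ngtdm_features(x))
  data.frame(family = family, feature = names(v), value = unname(v))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the full 90-feature static/parametric set
#'
#' Complete single-image pipeline: extract VOI values, discretise at the
#' fixed bin width, build the four texture matrices, and compute intensity
#' (18), shape (13), GLCM (22), GLRLM (16), GLSZM (16) and NGTDM (5)
#' features. Works identically on a static SUV image and a parametric
#' influx/metabolic-rate image given a scheme on that image's scale.
#'
#' @param image a [pet_image()], already resampled to the isotropic grid.
#' @param mask a [voi_mask()] on the image grid.
#' @param scheme a [discretisation_scheme()] (or bare bin width).
#' @return data.frame of 90 rows: family, feature, value.
#' @export
extract_static_feature_set <- function(image, mask, scheme) {
  if (is.numeric(scheme)) scheme <- discretisation_scheme(scheme)
  vals <- extract_voi_values(image, mask)$value
  dvoi <- suppressMessages(apply_fixed_width(vals, scheme))
  rbind(
    compute_family_features(
      list(values = vals, levels = dvoi$levels,
           voxel_volume_mm3 = prod(image$spacing)), "intensity"),
    compute_family_features(mask, "shape"),
    compute_family_features(build_glcm_3d(dvoi, mask), "glcm"),
    compute_family_features(build_glrlm_3d(dvoi, mask), "glrlm"),
    compute_family_features(build_glszm(dvoi, mask), "glszm"),
    compute_family_features(build_ngtdm(dvoi, mask), "ngtdm")
  )
}

#' Extract the 38 temporal-domain dynamic features
#'
#' Discretises each frame of the series inside the VOI with its own fixed
#' bin width, builds the causal temporal GLCM and the temporal GLRLM on the
#' shared grey-level range, and computes the 22 co-occurrence and 16
#' run-length features on them (the co-occurrence formulas handle the
#' asymmetric temporal matrix via separate row/column marginals).
#'
#' @param series a [dynamic_series()] on the common grid, >= 2 frames.
#' @param mask a [voi_mask()] on the series grid.
#' @param per_frame_widths one positive bin width per frame.
#' @return data.frame of 38 rows: family in dyn_glcm / dyn_glrlm, feature,
#'   value.
#' @export
extract_dynamic_feature_set <- function(series, mask, per_frame_widths) {
  if (n_frames(series$schedule) < 2L)
    stop("dynamic feature extraction needs at least 2 frames")
  disc <- discretise_frames(series, mask, per_frame_widths)
  tg <- build_temporal_glcm(disc$frames, disc$global_ng)
  tr <- build_temporal_glrlm(disc$frames, disc$global_ng)
  fg <- glcm_features(tg)
  fr <- glrlm_features(tr)
  rbind(
    data.frame(family = "dyn_glcm", feature = names(fg), value = unname(fg)),
    data.frame(family = "dyn_glrlm", feature = names(fr), value = unname(fr))
  )
}
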