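#' Voxelwise kinetic ground truth for the synthetic phantom
#'
#' Per-voxel irreversible-uptake parameters on a common grid: the influx
#' constant Ki (min^-1) and fractional blood volume vb, plus the plasma
#' glucose concentration and lumped constant needed to convert Ki to a
#' glucose metabolic rate.
#'
#' @param ki_map numeric 3D array, Ki in min^-1, all >= 0.
#' @param vb_map numeric 3D array on the same grid, blood volume fraction in
#'   `[0, 1]`.
#' @param plasma_glucose scalar, mmol/L.
#' @param lumped_constant scalar > 0 relating FDG flux to glucose flux;
#'   default 1.
#' @return object of class `kinetic_truth`.
#' @export
kinetic_ground_truth <- function(ki_map, vb_map, plasma_glucose = 5.0,
                                 lumped_constant = 1.0) {
  ki_map <- as.array(ki_map); vb_map <- as.array(vb_map)
  if (!identical(dim(ki_map), dim(vb_map)))
    stop("ki_map and vb_map must share one grid")
  if (any(ki_map < 0)) stop("Ki must be non-negative")
  if (any(vb_map < 0 | vb_map > 1)) stop("vb must lie in [0, 1]")
  if (lumped_constant <= 0) stop("lumped constant must be positive")
  structure(list(ki_map = ki_map, vb_map = vb_map,
                 plasma_glucose = plasma_glucose,
                 lumped_constant = lumped_constant),
            class = "kinetic_truth")
}

## run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a dynamic PET series from Patlak-linear kinetics
#'
#' Generates frame volumes under the irreversible-uptake model
#' `C_t(t) = Ki * int_0^t C_p(tau) dtau + vb * C_p(t)`, the model whose
#' graphical linearisation the Patlak analysis assumes. Each frame stores the
#' duration-weighted time average of `C_t` over its acquisition window
#' (activity-concentration convention), computed in closed form for analytic
#' plasma curves, with optional zero-mean Gaussian noise whose standard
#' deviation is `noise_sd` times the local noiseless signal.
#'
#' @param truth a [kinetic_ground_truth()].
#' @param plasma a [plasma_curve()] covering the schedule.
#' @param schedule a [frame_schedule()].
#' @param noise_sd fractional noise level >= 0 (0 = noiseless).
#' @param seed integer; fully determines the noise realisation.
#' @param spacing,origin grid geometry (mm); default isotropic 3.38 mm, the
#'   common resampling target for the two-scanner acquisition this emulates.
#' @return a [dynamic_series()] in the plasma curve's activity units.
#' @export
simulate_dynamic_series <- function(truth, plasma, schedule, noise_sd = 0,
                                    seed = 1L,
                                    spacing = c(3.38, 3.38, 3.38),
                                    origin = c(0, 0, 0)) {
  stopifnot(inherits(truth, "kinetic_truth"),
            inherits(plasma, "plasma_curve"),
            inherits(schedule, "frame_schedule"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  end_min <- (schedule$starts[n_frames(schedule)] +
                schedule$durations[n_frames(schedule)]) / 60
  if (is.null(plasma$params) &&
      end_min > plasma$times[length(plasma$times)] + 1e-9)
    stop("schedule extends beyond plasma curve support")
  fa <- plasma_frame_averages(plasma, schedule)
  d <- dim(truth$ki_map)
  nt <- n_frames(schedule)
  frames <- array(0, dim = c(d, nt))
  for (f in seq_len(nt))
    frames[, , , f] <- truth$ki_map * fa$avg_integral[f] +
      truth$vb_map * fa$avg_conc[f]
  if (noise_sd > 0) {
    frames <- with_seed(seed, {
      frames + stats::rnorm(length(frames)) * noise_sd * frames
    })
  }
  dynamic_series(frames, schedule, spacing = spacing, origin = origin,
                 units = "Bq/mL")
}

#' Sum consecutive frames into longer frames
#'
#' Combines each group of `group_size` contiguous frames into one frame whose
#' value is the duration-weighted mean of the group (preserving the
#' activity-concentration convention) and whose duration is the group total.
#' Summing the sixteen 150 s frames pairwise yields the eight 300 s frames.
#'
#' @param series a [dynamic_series()].
#' @param group_size integer; must divide the frame count, and frames within
#'   a group must be contiguous in time.
#' @return a [dynamic_series()] with `n/group_size` frames.
#' @export
sum_frames <- function(series, group_size) {
  stopifnot(inherits(series, "dynamic_series"))
  group_size <- as.integer(group_size)
  nt <- n_frames(series$schedule)
  if (group_size < 1L) stop("group_size must be >= 1")
  if (nt %% group_size != 0L)
    stop("frame count ", nt, " not divisible by group_size ", group_size)
  if (group_size == 1L) return(series)
  st <- series$schedule$starts; du <- series$schedule$durations
  grp <- rep(seq_len(nt / group_size), each = group_size)
  for (g in unique(grp)) {
    ix <- which(grp == g)
    ends <- st[ix] + du[ix]
    if (any(abs(ends[-length(ix)] - st[ix[-1]]) > 1e-9))
      stop("frames within group ", g, " are not contiguous")
  }
  new_starts <- tapply(st, grp, min)
  new_dur <- tapply(du, grp, sum)
  d <- dim(series$frames)
  out <- array(0, dim = c(d[1:3], nt / group_size))
  for (g in seq_len(nt / group_size)) {
    ix <- which(grp == g)
    w <- du[ix] / sum(du[ix])
    acc <- array(0, dim = d[1:3])
    for (m in seq_along(ix))
      acc <- acc + w[m] * series$frames[, , , ix[m], drop = TRUE]
    out[, , , g] <- acc
  }
  dynamic_series(out, frame_schedule(as.numeric(new_starts),
                                     as.numeric(new_dur)),
                 spacing = series$spacing, origin = series$origin,
                 units = series$units)
}

#' Derive a static image from a dynamic series
#'
#' Duration-weighted mean of the frames covering `window` (seconds p.i.);
#' the PET convention for a static reconstruction over a late uptake window.
#'
#' @param series a [dynamic_series()].
#' @param window numeric length-2, `c(start_s, end_s)`; must be exactly tiled
#'   by the schedule's frames.
#' @return a [pet_image()] in the series' units.
#' @export
derive_static_image <- function(series, window) {
  stopifnot(inherits(series, "dynamic_series"), length(window) == 2L)
  st <- series$schedule$starts; du <- series$schedule$durations
  inside <- which(st >= window[1] - 1e-9 & st + du <= window[2] + 1e-9)
  if (length(inside) == 0L) stop("no frames inside window")
  if (abs(sum(du[inside]) - (window[2] - window[1])) > 1e-6)
    stop("window not exactly covered by schedule frames")
  w <- du[inside] / sum(du[inside])
  d <- dim(series$frames)
  acc <- array(0, dim = d[1:3])
  for (m in seq_along(inside))
    acc <- acc + w[m] * series$frames[, , , inside[m], drop = TRUE]
  pet_image(acc, series$spacing, series$origin, series$units)
}

#' Default phantom geometry: ellipsoidal lesion with focal hot spot
#'
#' Builds the voxelwise ground-truth maps the simulator consumes: an
#' ellipsoidal lesion (>= 500 voxels at the default size) with a smooth
#' radial Ki gradient plus a higher-Ki focal sub-region, inside a low-uptake
#' background. Provides genuine spatial and temporal texture for feature
#' extraction.
#'
#' @param dims grid size in voxels (default 24 x 24 x 18).
#' @param radii lesion semi-axes in voxels.
#' @param ki_lesion peak lesion Ki at the centre, min^-1.
#' @param ki_background background Ki, min^-1.
#' @param ki_focal Ki inside the focal sub-region, min^-1.
#' @param vb_lesion,vb_background blood volume fractions.
#' @param plasma_glucose,lumped_constant as in [kinetic_ground_truth()].
#' @return list with elements `truth` ([kinetic_ground_truth()]) and `mask`
#'   ([voi_mask()], the lesion ellipsoid).
#' @export
phantom_geometry <- function(dims = c(24, 24, 18),
                             radii = c(6.4, 5.4, 4.4),
                             ki_lesion = 0.03, ki_background = 0.002,
                             ki_focal = 0.055,
                             vb_lesion = 0.05, vb_background = 0.03,
                             plasma_glucose = 5.0, lumped_constant = 1.0) {
  ctr <- (dims + 1) / 2
  ii <- slice.index(array(0, dims), 1)
  jj <- slice.index(array(0, dims), 2)
  kk <- slice.index(array(0, dims), 3)
  r2 <- ((ii - ctr[1]) / radii[1])^2 + ((jj - ctr[2]) / radii[2])^2 +
    ((kk - ctr[3]) / radii[3])^2
  lesion <- r2 <= 1
  if (sum(lesion) < 8) stop("lesion too small for the requested grid")
  ## smooth centre-to-rim Ki gradient
  ki <- array(ki_background, dims)
  ki[lesion] <- ki_background +
    (ki_lesion - ki_background) * (1 - 0.6 * sqrt(r2[lesion]))
  ## focal hot sub-region offset towards +x
  foc_ctr <- ctr + c(radii[1] * 0.45, 0, 0)
  f2 <- ((ii - foc_ctr[1]) / (radii[1] * 0.35))^2 +
    ((jj - foc_ctr[2]) / (radii[2] * 0.35))^2 +
    ((kk - foc_ctr[3]) / (radii[3] * 0.35))^2
  ki[lesion & f2 <= 1] <- ki_focal
  vb <- array(vb_background, dims)
  vb[lesion] <- vb_lesion
  list(truth = kinetic_ground_truth(ki, vb, plasma_glucose, lumped_constant),
       mask = voi_mask(lesion, spacing = c(3.38, 3.38, 3.38)))
}

#' Simulate a complete 4D phantom
#'
#' One call producing everything a lesion analysis needs: ground-truth maps,
#' VOI mask, plasma input, the dynamic series over 10-50 min p.i., and a
#' late static image (50-60 min window) simulated from the same kinetics.
#' Regeneration with the same seed is bit-identical.
#'
#' @param seed integer; drives the noise realisation and, for cohort
#'   variation, can be combined with jittered geometry by the caller.
#' @param noise_sd fractional Gaussian noise level (0 = noiseless).
#' @param preset frame schedule preset, see [standard_schedule()].
#' @param geometry list from [phantom_geometry()]; default geometry if NULL.
#' @param plasma a [plasma_curve()]; a default three-exponential input if
#'   NULL.
#' @return object of class `dynamic_phantom`: list(series, static, truth,
#'   mask, plasma, schedule, seed).
#' @export
simulate_phantom <- function(seed = 1L, noise_sd = 0,
                             preset = "16x150", geometry = NULL,
                             plasma = NULL) {
  schedule <- standard_schedule(preset)
  if (is.null(geometry)) geometry <- phantom_geometry()
  if (is.null(plasma))
    plasma <- simulate_plasma_input(c(800, 100, 60), c(4, 0.3, 0.01),
                                    schedule)
  series <- simulate_dynamic_series(geometry$truth, plasma, schedule,
                                    noise_sd = noise_sd, seed = seed)
  static_sched <- frame_schedule(3000, 600)
  static_series <- simulate_dynamic_series(geometry$truth, plasma,
                                           static_sched,
                                           noise_sd = noise_sd,
                                           seed = seed + 104729L)
  static <- derive_static_image(static_series, c(3000, 3600))
  structure(list(series = series, static = static, truth = geometry$truth,
                 mask = geometry$mask, plasma = plasma,
                 schedule = schedule, seed = as.integer(seed)),
            class = "dynamic_phantom")
}

#' Simulate a cohort of heterogeneous phantom lesions
#'
#' Draws `n` lesions whose geometry (semi-axes), kinetic levels and plasma
#' input are jittered around the defaults, each with its own noise seed, so
#' cohort-level feature tables show genuine between-lesion variation. The
#' jitters are deterministic functions of `seed`.
#'
#' @param n number of lesions.
#' @param seed integer master seed.
#' @param noise_sd fractional noise per lesion.
#' @return list of `n` [simulate_phantom()] objects.
#' @export
simulate_cohort <- function(n = 20, seed = 1L, noise_sd = 0.05) {
  params <- with_seed(seed, {
    list(rad = matrix(stats::runif(3 * n, 0.85, 1.25), ncol = 3),
         kil = stats::runif(n, 0.02, 0.045),
         kif = stats::runif(n, 1.4, 2.0),
         vbl = stats::runif(n, 0.03, 0.08),
         amp = matrix(stats::runif(3 * n, 0.8, 1.2), ncol = 3))
  })
  lapply(seq_len(n), function(i) {
    geom <- phantom_geometry(
      radii = c(6.4, 5.4, 4.4) * params$rad[i, ],
      ki_lesion = params$kil[i],
      ki_focal = params$kil[i] * params$kif[i],
      vb_lesion = params$vbl[i])
    sch <- standard_schedule("16x150")
    plasma <- simulate_plasma_input(
      c(800, 100, 60) * params$amp[i, ], c(4, 0.3, 0.01), sch)
    simulate_phantom(seed = seed * 1000L + i, noise_sd = noise_sd,
                     geometry = geom, plasma = plasma)
  })
}
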