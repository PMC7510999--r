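#' Tissue time-activity curve of a VOI or single voxel
#'
#' Frame-averaged activity concentrations paired with their schedule; the
#' nominal sample time of each frame is its midpoint.
#'
#' @param values numeric, one mean concentration per frame.
#' @param schedule a [frame_schedule()].
#' @return object of class `tissue_curve`.
#' @export
tissue_curve <- function(values, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(values) != n_frames(schedule))
    stop("need one tissue value per frame")
  structure(list(values = as.numeric(values), schedule = schedule,
                 times_min = frame_midpoints_min(schedule)),
            class = "tissue_curve")
}

#' Settings for Patlak parametric analysis
#'
#' @param plasma_glucose plasma glucose, mmol/L (equivalently umol/mL).
#' @param lumped_constant scale factor relating FDG flux to glucose flux,
#'   > 0; default 1.
#' @param t_star start of the linear fit window in normalised Patlak time
#'   (minutes), default 15.
#' @param window_end end of the fit window in normalised Patlak time,
#'   default 60.
#' @return object of class `parametric_settings`.
#' @export
parametric_settings <- function(plasma_glucose = 5.0, lumped_constant = 1.0,
                                t_star = 15, window_end = 60) {
  if (lumped_constant <= 0) stop("lumped constant must be positive")
  if (t_star >= window_end) stop("t_star must precede the window end")
  structure(list(plasma_glucose = plasma_glucose,
                 lumped_constant = lumped_constant,
                 t_star = t_star, window_end = window_end),
            class = "parametric_settings")
}

#' Patlak graphical transform
#'
#' Maps each frame to a point on the Patlak plot:
#' `x = int_0^t C_p / C_p(t)` (normalised Patlak time, minutes) and
#' `y = C_t(t) / C_p(t)`. For frame-averaged tissue data the plasma
#' quantities are duration-weighted frame averages of `C_p` and of its
#' running integral, which makes the identity
#' `y = Ki * x + vb` hold exactly for irreversible-uptake kinetics. Frames
#' where the averaged plasma concentration is not positive are dropped with
#' a message.
#'
#' @param tissue a [tissue_curve()].
#' @param plasma a [plasma_curve()] covering the schedule.
#' @return data.frame with columns `t_min` (frame midpoint), `x`, `y`.
#' @export
patlak_transform <- function(tissue, plasma) {
  stopifnot(inherits(tissue, "tissue_curve"),
            inherits(plasma, "plasma_curve"))
  fa <- plasma_frame_averages(plasma, tissue$schedule)
  ok <- fa$avg_conc > 0
  if (!all(ok))
    message(sum(!ok), " frame(s) dropped: non-positive plasma concentration")
  data.frame(t_min = tissue$times_min[ok],
             x = fa$avg_integral[ok] / fa$avg_conc[ok],
             y = tissue$values[ok] / fa$avg_conc[ok])
}

#' Fit the Patlak slope (influx constant Ki)
#'
#' Ordinary least squares through the Patlak points whose normalised time
#' falls in `[t_star, window_end]`. The slope is the influx constant Ki
#' (min^-1); the intercept estimates the distribution volume term.
#'
#' @param points data.frame from [patlak_transform()].
#' @param settings a [parametric_settings()].
#' @return object of class `patlak_fit`: `ki`, `intercept`, `window`,
#'   `n_points`, `residual_rms`.
#' @export
fit_patlak_slope <- function(points, settings = parametric_settings()) {
  sel <- points$x >= settings$t_star & points$x <= settings$window_end
  if (sum(sel) < 2L)
    stop("fewer than 2 Patlak points in the fit window [",
         settings$t_star, ", ", settings$window_end, "]")
  x <- points$x[sel]; y <- points$y[sel]
  mx <- mean(x); my <- mean(y)
  ki <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  b0 <- my - ki * mx
  res <- y - (b0 + ki * x)
  structure(list(ki = ki, intercept = b0,
                 window = c(settings$t_star, settings$window_end),
                 n_points = sum(sel),
                 residual_rms = sqrt(mean(res^2))),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf(
    "<patlak_fit> Ki = %.6g min^-1, intercept = %.4g (%d points, rms %.3g)\n",
    x$ki, x$intercept, x$n_points, x$residual_rms))
  invisible(x)
}

#' Compute voxelwise Patlak parametric images
#'
#' Applies the Patlak transform and linear fit to every voxel's
#' time-activity curve (vectorised: the Patlak abscissa depends only on the
#' plasma curve, so one normal-equation solve covers all voxels) and
#' converts the influx constant to a glucose metabolic rate,
#' `MRglc = Ki * plasma_glucose / lumped_constant` (umol/mL/min when glucose
#' is in mmol/L and Ki in min^-1). Voxels whose fit is impossible are set to
#' 0 and counted.
#'
#' @param series a [dynamic_series()].
#' @param plasma a [plasma_curve()].
#' @param settings a [parametric_settings()].
#' @return list of class `patlak_parametric`: `ki` and `mrglc`
#'   ([pet_image()]s), `intercept` array, `n_frames_used`.
#' @export
compute_parametric_image <- function(series, plasma,
                                     settings = parametric_settings()) {
  stopifnot(inherits(series, "dynamic_series"))
  fa <- plasma_frame_averages(plasma, series$schedule)
  ok <- fa$avg_conc > 0
  x <- fa$avg_integral[ok] / fa$avg_conc[ok]
  sel <- which(x >= settings$t_star & x <= settings$window_end)
  if (length(sel) < 2L)
    stop("fewer than 2 frames in the Patlak fit window")
  xw <- x[sel]
  d <- dim(series$frames)
  nt <- d[4]
  Y <- matrix(series$frames, nrow = prod(d[1:3]), ncol = nt)[, which(ok)[sel],
                                                             drop = FALSE]
  Y <- sweep(Y, 2, fa$avg_conc[ok][sel], `/`)
  mx <- mean(xw)
  ki <- as.vector((Y %*% (xw - mx)) / sum((xw - mx)^2))
  b0 <- rowMeans(Y) - ki * mx
  ki_img <- array(ki, dim = d[1:3])
  mrglc <- ki_img * settings$plasma_glucose / settings$lumped_constant
  structure(list(
    ki = pet_image(ki_img, series$spacing, series$origin, "min^-1"),
    mrglc = pet_image(mrglc, series$spacing, series$origin, "umol/mL/min"),
    intercept = array(b0, dim = d[1:3]),
    n_frames_used = length(sel)),
    class = "patlak_parametric")
}
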