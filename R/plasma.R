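#' Plasma input curve
#'
#' Arterial/image-derived plasma time-activity curve. Two flavours share one
#' class: an analytic exponential mixture `c(t) = sum_i A_i exp(-lambda_i t)`
#' (created by [simulate_plasma_input()]), which carries closed-form values
#' and running integrals, or a sampled curve read from CSV, evaluated by
#' linear interpolation and integrated by the trapezoid rule on the samples.
#' Times are minutes post-injection; concentrations are activity per mL.
#'
#' @param times numeric, sample times in minutes, strictly increasing.
#' @param conc numeric, concentrations, all >= 0.
#' @param params optional list(amplitudes, rates) of the analytic form.
#' @return object of class `plasma_curve`.
#' @export
plasma_curve <- function(times, conc, params = NULL) {
  times <- as.numeric(times); conc <- as.numeric(conc)
  if (length(times) != length(conc)) stop("times and conc lengths differ")
  if (any(diff(times) <= 0)) stop("sample times must be strictly increasing")
  if (any(conc < 0)) stop("plasma concentrations must be non-negative")
  structure(list(times = times, conc = conc, params = params),
            class = "plasma_curve")
}

#' @export
print.plasma_curve <- function(x, ...) {
  cat(sprintf("<plasma_curve> %d samples on [%.3g, %.3g] min%s\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              if (is.null(x$params)) "" else
                sprintf(", analytic (%d exponential terms)",
                        length(x$params$amplitudes))))
  invisible(x)
}

#' Simulate an analytic plasma input function
#'
#' Builds a plasma curve of the form `c(t) = sum_i A_i exp(-lambda_i t)`
#' (t in minutes; `lambda_i = 0` gives a constant term), sampled at the frame
#' midpoints of `schedule`. The analytic parameters travel with the curve so
#' that concentrations and running integrals are evaluated in closed form at
#' arbitrary times.
#'
#' @param amplitudes numeric, `A_i` >= 0 (activity per mL).
#' @param rates numeric, decay rates `lambda_i` >= 0 in min^-1.
#' @param schedule a [frame_schedule()].
#' @return a [plasma_curve()] with analytic parameters attached.
#' @examples
#' sch <- standard_schedule("16x150")
#' cp <- simulate_plasma_input(c(800, 100, 60), c(4, 0.3, 0.01), sch)
#' plasma_integral(cp, 30)  # closed-form running integral at 30 min
#' @export
simulate_plasma_input <- function(amplitudes, rates, schedule) {
  amplitudes <- as.numeric(amplitudes); rates <- as.numeric(rates)
  if (length(amplitudes) == 0L) stop("need at least one exponential term")
  if (length(amplitudes) != length(rates))
    stop("amplitudes and rates lengths differ")
  if (any(amplitudes < 0))
    stop("negative amplitudes would produce negative concentrations")
  if (any(rates < 0)) stop("rates must be non-negative")
  params <- list(amplitudes = amplitudes, rates = rates)
  t_mid <- frame_midpoints_min(schedule)
  plasma_curve(t_mid, exp_mixture_conc(params, t_mid), params = params)
}

## closed-form concentration / running integral of an exponential mixture
exp_mixture_conc <- function(params, t) {
  out <- numeric(length(t))
  for (i in seq_along(params$amplitudes))
    out <- out + params$amplitudes[i] * exp(-params$rates[i] * t)
  out
}

exp_mixture_integral <- function(params, t) {
  out <- numeric(length(t))
  for (i in seq_along(params$amplitudes)) {
    A <- params$amplitudes[i]; l <- params$rates[i]
    out <- out + if (l == 0) A * t else (A / l) * (1 - exp(-l * t))
  }
  out
}

## double integral: int_0^T [ int_0^tau c ] dtau, closed form
exp_mixture_integral2 <- function(params, t) {
  out <- numeric(length(t))
  for (i in seq_along(params$amplitudes)) {
    A <- params$amplitudes[i]; l <- params$rates[i]
    out <- out + if (l == 0) A * t^2 / 2 else
      (A / l) * (t - (1 - exp(-l * t)) / l)
  }
  out
}

#' Evaluate a plasma curve at arbitrary times (minutes)
#'
#' Analytic curves use the closed form; sampled curves are linearly
#' interpolated (constant extrapolation at the ends).
#' @param curve a `plasma_curve`.
#' @param t numeric, minutes.
#' @export
plasma_conc <- function(curve, t) {
  if (!is.null(curve$params)) return(exp_mixture_conc(curve$params, t))
  stats::approx(curve$times, curve$conc, xout = t, rule = 2)$y
}

#' Running integral of a plasma curve from 0 to t (minutes)
#'
#' Closed form for analytic curves; trapezoid rule (with the curve assumed
#' linear from (0, c(0)) to the first sample) for sampled curves.
#' @param curve a `plasma_curve`.
#' @param t numeric, minutes; must not exceed the sampled support for
#'   non-analytic curves.
#' @export
plasma_integral <- function(curve, t) {
  if (!is.null(curve$params)) return(exp_mixture_integral(curve$params, t))
  tmax <- curve$times[length(curve$times)]
  if (any(t > tmax + 1e-9))
    stop("requested integral beyond plasma curve support (", tmax, " min)")
  grid_t <- c(0, curve$times)
  grid_c <- c(plasma_conc(curve, 0), curve$conc)
  cum <- c(0, cumsum(diff(grid_t) * (grid_c[-1] + grid_c[-length(grid_c)]) / 2))
  vapply(t, function(ti) {
    j <- findInterval(ti, grid_t)
    ci <- plasma_conc(curve, ti)
    cum[j] + (ti - grid_t[j]) * (grid_c[j] + ci) / 2
  }, numeric(1))
}

## duration-weighted frame averages of c and of its running integral,
## per frame of `schedule`; exact for analytic curves
plasma_frame_averages <- function(curve, schedule) {
  t0 <- schedule$starts / 60
  t1 <- (schedule$starts + schedule$durations) / 60
  dur <- t1 - t0
  if (!is.null(curve$params)) {
    avg_c <- (exp_mixture_integral(curve$params, t1) -
                exp_mixture_integral(curve$params, t0)) / dur
    avg_I <- (exp_mixture_integral2(curve$params, t1) -
                exp_mixture_integral2(curve$params, t0)) / dur
  } else {
    ## numeric quadrature on a fine grid inside each frame
    avg_c <- numeric(length(dur)); avg_I <- numeric(length(dur))
    for (f in seq_along(dur)) {
      g <- seq(t0[f], t1[f], length.out = 65)
      cg <- plasma_conc(curve, g)
      Ig <- plasma_integral(curve, g)
      w <- diff(g)
      avg_c[f] <- sum(w * (cg[-1] + cg[-65]) / 2) / dur[f]
      avg_I[f] <- sum(w * (Ig[-1] + Ig[-65]) / 2) / dur[f]
    }
  }
  list(avg_conc = avg_c, avg_integral = avg_I)
}

#' Read / write a plasma curve as CSV (columns time_min, concentration)
#' @param curve a `plasma_curve`.
#' @param path file path.
#' @export
write_plasma_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_min = curve$times,
                              concentration = curve$conc),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plasma_csv
#' @export
read_plasma_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_min", "concentration") %in% names(d)))
  plasma_curve(d$time_min, d$concentration)
}
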