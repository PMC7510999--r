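#' Frame schedule for a dynamic acquisition
#'
#' Start times and durations (seconds post-injection) of each frame. Frames
#' must not overlap; gaps are allowed.
#'
#' @param starts numeric, frame start times in seconds, strictly increasing.
#' @param durations numeric, frame durations in seconds, all > 0.
#' @return object of class `frame_schedule`.
#' @export
frame_schedule <- function(starts, durations) {
  starts <- as.numeric(starts); durations <- as.numeric(durations)
  if (length(starts) == 0L) stop("schedule must contain at least one frame")
  if (length(starts) != length(durations))
    stop("starts and durations must have equal length")
  if (any(diff(starts) <= 0)) stop("frame starts must be strictly increasing")
  if (any(durations <= 0)) stop("frame durations must be positive")
  ends <- starts + durations
  if (any(ends[-length(ends)] > starts[-1] + 1e-9))
    stop("frames overlap")
  structure(list(starts = starts, durations = durations),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %g-%g s p.i.\n",
              length(x$starts), x$starts[1],
              x$starts[length(x$starts)] + x$durations[length(x$durations)]))
  invisible(x)
}

#' Number of frames in a schedule
#' @param schedule a `frame_schedule`.
#' @export
n_frames <- function(schedule) length(schedule$starts)

#' Frame midpoint times in minutes post-injection
#' @param schedule a `frame_schedule`.
#' @export
frame_midpoints_min <- function(schedule) {
  (schedule$starts + schedule$durations / 2) / 60
}

#' Standard dynamic frame schedules over the 10-50 min window
#'
#' The two framings of the same 40-minute acquisition window used throughout
#' the package: sixteen 150 s frames or eight 300 s frames, both starting at
#' 10 min post-injection. Pairwise summing of the 150 s schedule with
#' [sum_frames()] reproduces the 300 s schedule.
#'
#' @param preset `"16x150"` or `"8x300"`.
#' @return a [frame_schedule()].
#' @export
standard_schedule <- function(preset = c("16x150", "8x300")) {
  preset <- match.arg(preset)
  if (preset == "16x150")
    frame_schedule(600 + 150 * (0:15), rep(150, 16))
  else
    frame_schedule(600 + 300 * (0:7), rep(300, 8))
}

#' Read / write a frame schedule as CSV
#'
#' CSV columns: `frame_index`, `start_s`, `duration_s`.
#' @param schedule a `frame_schedule`.
#' @param path file path.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(
    data.frame(frame_index = seq_along(schedule$starts) - 1L,
               start_s = schedule$starts,
               duration_s = schedule$durations),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("start_s", "duration_s") %in% names(d)))
  d <- d[order(d$start_s), ]
  frame_schedule(d$start_s, d$duration_s)
}
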