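#' Freedman-Diaconis bin width from cohort-mean IQR and voxel count
#'
#' `width = 2 * IQR * N^(-1/3)` with IQR the mean interquartile range and N
#' the mean number of VOI voxels across the cohort.
#'
#' @param mean_iqr positive scalar, intensity units.
#' @param mean_n mean voxel count, >= 1.
#' @return bin width in the intensity units of `mean_iqr`.
#' @examples
#' freedman_diaconis_width(4, 64)      # 2
#' freedman_diaconis_width(0.5, 1000)  # 0.1
#' @export
freedman_diaconis_width <- function(mean_iqr, mean_n) {
  if (mean_iqr <= 0) stop("degenerate population: mean IQR must be > 0")
  if (mean_n < 1) stop("mean_n must be >= 1")
  2 * mean_iqr * mean_n^(-1 / 3)
}

#' Population-based fixed bin width for a cohort of VOIs
#'
#' Computes the interquartile range and voxel count of each VOI's intensity
#' values, averages both across the cohort, and applies the
#' Freedman-Diaconis rule. Used once per image type (static, parametric, or
#' each dynamic frame) so that all lesions share one absolute-scale
#' discretisation.
#'
#' @param cohort_vois list of numeric vectors, one per lesion; each with at
#'   least 4 voxels.
#' @return bin width (intensity units).
#' @export
population_width <- function(cohort_vois) {
  if (length(cohort_vois) == 0L) stop("empty cohort")
  if (any(vapply(cohort_vois, length, 1L) < 4L))
    stop("each VOI needs at least 4 voxels for an IQR")
  iqrs <- vapply(cohort_vois, function(v)
    stats::IQR(v, type = 7), numeric(1))
  ns <- vapply(cohort_vois, length, 1L)
  freedman_diaconis_width(mean(iqrs), mean(ns))
}

#' Fixed-bin-width discretisation scheme
#'
#' Grey level of an intensity x is `floor((x - anchor) / bin_width) + 1`.
#' Bin edges are anchored at `anchor` (default 0), not at the VOI minimum,
#' so that a given grey level means the same absolute intensity bin in every
#' lesion and every frame.
#'
#' @param bin_width positive scalar, intensity units.
#' @param anchor intensity at which bin edges start; default 0.
#' @return object of class `discretisation_scheme`.
#' @export
discretisation_scheme <- function(bin_width, anchor = 0) {
  if (bin_width <= 0) stop("bin_width must be positive")
  structure(list(bin_width = bin_width, anchor = anchor),
            class = "discretisation_scheme")
}

#' Discretise VOI intensity values into integer grey levels
#'
#' Negative excursions below the anchor (possible in reconstructed PET
#' backgrounds) are clamped to the anchor when `clamp_negative = TRUE`
#' (default), with the clamped count reported via a message; otherwise a
#' value below the anchor is an error naming the first offending voxel.
#'
#' @param values numeric vector of VOI intensities.
#' @param scheme a [discretisation_scheme()] (or a bare positive width).
#' @param clamp_negative clamp values below the anchor to the anchor.
#' @return object of class `discretised_voi`: integer `levels` (1..Ng),
#'   `ng` (highest occupied level) and the `scheme`.
#' @export
apply_fixed_width <- function(values, scheme, clamp_negative = TRUE) {
  if (is.numeric(scheme)) scheme <- discretisation_scheme(scheme)
  stopifnot(inherits(scheme, "discretisation_scheme"))
  if (!all(is.finite(values))) stop("values must be finite")
  below <- values < scheme$anchor
  if (any(below)) {
    if (!clamp_negative)
      stop("value below anchor at voxel ", which(below)[1],
           " (", values[which(below)[1]], " < ", scheme$anchor, ")")
    message(sum(below), " voxel(s) below anchor clamped to ", scheme$anchor)
    values[below] <- scheme$anchor
  }
  lv <- as.integer(floor((values - scheme$anchor) / scheme$bin_width)) + 1L
  structure(list(levels = lv, ng = max(lv), scheme = scheme),
            class = "discretised_voi")
}

#' Discretise every frame of a dynamic series inside the VOI
#'
#' Each frame gets its own fixed bin width (population-based, computed per
#' frame across the cohort); the global grey-level count Ng is the maximum
#' over frames and defines the shared dimension of the temporal matrices, so
#' that a level indexes the same absolute bin in every frame.
#'
#' @param series a [dynamic_series()].
#' @param mask a [voi_mask()] on the series grid.
#' @param per_frame_widths numeric vector, one positive width per frame.
#' @param anchor bin-edge anchor, default 0.
#' @return list with `frames` (list of [apply_fixed_width()] results, one
#'   per frame, voxel-aligned) and `global_ng`.
#' @export
discretise_frames <- function(series, mask, per_frame_widths, anchor = 0) {
  stopifnot(inherits(series, "dynamic_series"), inherits(mask, "voi_mask"))
  nt <- n_frames(series$schedule)
  if (length(per_frame_widths) != nt)
    stop("need one width per frame: ", nt, " frames, ",
         length(per_frame_widths), " widths")
  if (any(per_frame_widths <= 0)) stop("widths must be positive")
  frames <- lapply(seq_len(nt), function(t) {
    vals <- extract_voi_values(get_frame(series, t), mask)$value
    suppressMessages(
      apply_fixed_width(vals, discretisation_scheme(per_frame_widths[t],
                                                    anchor)))
  })
  list(frames = frames, global_ng = max(vapply(frames, `[[`, 1L, "ng")))
}

#' Read / write discretisation widths as a JSON config
#'
#' Schema: `{"widths": {"static": w, "parametric": w, "frames": [w, ...]}}`.
#' @param widths list with elements `static`, `parametric`, `frames`.
#' @param path JSON file path.
#' @export
write_widths_json <- function(widths, path) {
  jsonlite::write_json(list(widths = widths), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_widths_json
#' @export
read_widths_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)$widths
}
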