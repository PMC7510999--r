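#' 3D PET image container
#'
#' Lightweight container for a scalar 3D volume on a regular grid: a numeric
#' array plus physical spacing (mm), world origin of the first voxel centre
#' (mm) and a units tag. All package operations treat voxel (1,1,1) as sitting
#' at `origin` and voxel centres at `origin + (index - 1) * spacing`.
#'
#' @param values numeric 3D array, finite.
#' @param spacing numeric length-3, mm per axis, all > 0.
#' @param origin numeric length-3, mm; world position of the first voxel
#'   centre. Default c(0, 0, 0).
#' @param units character tag, e.g. `"Bq/mL"`, `"SUV g/mL"`, `"min^-1"`.
#' @return object of class `pet_image`.
#' @export
pet_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      units = "arbitrary") {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("pet_image requires a 3D array, got ", length(dim(values)), " dims")
  if (!all(is.finite(values)))
    stop("pet_image values must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  structure(
    list(values = values, spacing = spacing,
         origin = as.numeric(origin), units = units),
    class = "pet_image"
  )
}

#' @export
print.pet_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pet_image> %dx%dx%d voxels, spacing %s mm, units %s\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = "x"), x$units))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary volume of interest mask
#'
#' @param values logical or 0/1 numeric 3D array; must contain at least one
#'   TRUE voxel.
#' @param spacing,origin grid geometry as in [pet_image()].
#' @return object of class `voi_mask`; `values` stored as logical.
#' @export
voi_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("voi_mask requires a 3D array")
  u <- unique(as.vector(values))
  if (!all(u %in% c(0, 1, TRUE, FALSE)))
    stop("mask is not binary; offending values: ",
         paste(utils::head(setdiff(u, c(0, 1)), 5), collapse = ", "))
  values <- array(as.logical(values), dim = dim(values))
  if (!any(values)) stop("mask is empty")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "voi_mask"
  )
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s voxels in VOI of %s grid\n",
              sum(x$values), paste(dim(x$values), collapse = "x")))
  invisible(x)
}

#' Dynamic PET series (4D volume + frame schedule)
#'
#' Ordered 3D frames sharing one grid, with a [frame_schedule()] giving the
#' acquisition window of each frame. Voxel values are time-averaged activity
#' concentration over the frame window (the reconstructed-PET convention),
#' not integrated counts.
#'
#' @param frames 4D numeric array (x, y, z, t) or list of 3D arrays.
#' @param schedule a [frame_schedule()]; length must equal the frame count.
#' @param spacing,origin,units grid geometry as in [pet_image()].
#' @return object of class `dynamic_series`.
#' @export
dynamic_series <- function(frames, schedule, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0), units = "Bq/mL") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("all frames must share one grid")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 4L)
    stop("frames must form a 4D array (x, y, z, t)")
  if (dim(frames)[4] != n_frames(schedule))
    stop("frame count (", dim(frames)[4], ") does not match schedule length (",
         n_frames(schedule), ")")
  structure(
    list(frames = frames, schedule = schedule,
         spacing = as.numeric(spacing), origin = as.numeric(origin),
         units = units),
    class = "dynamic_series"
  )
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<dynamic_series> %dx%dx%d voxels x %d frames, %s\n",
              d[1], d[2], d[3], d[4], x$units))
  print(x$schedule)
  invisible(x)
}

#' Extract a single frame as a [pet_image()]
#' @param series a `dynamic_series`.
#' @param t frame index (1-based).
#' @export
get_frame <- function(series, t) {
  stopifnot(inherits(series, "dynamic_series"))
  if (t < 1 || t > dim(series$frames)[4]) stop("frame index out of range")
  pet_image(series$frames[, , , t, drop = TRUE], series$spacing,
            series$origin, series$units)
}

#' Extract VOI voxel values in a deterministic order
#'
#' Returns one value per mask voxel together with its voxel coordinates, in
#' column-major (x-fastest) lexicographic order. The same order is used by
#' every operation in the package, so per-frame value vectors from
#' [get_frame()] of one series are voxel-aligned.
#'
#' @param image a `pet_image` (or bare 3D array on the mask grid).
#' @param mask a `voi_mask` on the same grid.
#' @return data.frame with columns i, j, k (1-based voxel indices) and value.
#' @export
extract_voi_values <- function(image, mask) {
  vals <- if (inherits(image, "pet_image")) image$values else as.array(image)
  stopifnot(inherits(mask, "voi_mask"))
  if (!identical(dim(vals), dim(mask$values)))
    stop("image and mask grids differ: ",
         paste(dim(vals), collapse = "x"), " vs ",
         paste(dim(mask$values), collapse = "x"))
  idx <- which(mask$values)
  if (length(idx) == 0L) stop("empty image/mask intersection")
  co <- arrayInd(idx, dim(vals))
  data.frame(i = co[, 1], j = co[, 2], k = co[, 3], value = vals[idx])
}
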