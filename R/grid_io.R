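#' Read a 3D volume or mask from NIfTI
#'
#' Spacing is taken from the NIfTI pixdim and the world origin from the
#' translation column of the xform; only axis-aligned grids are supported.
#' Masks are validated to be strictly binary.
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @param kind `"image"` or `"mask"`.
#' @param units units tag to attach (images only); NIfTI itself does not
#'   carry PET units.
#' @return a [pet_image()] or [voi_mask()].
#' @export
read_volume <- function(path, kind = c("image", "mask"),
                        units = "arbitrary") {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  a <- strip_nifti_attrs(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L)
    a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop("expected a 3D volume, got ", length(dim(a)),
         " dims; use read_dynamic_series() for 4D files")
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  if (kind == "mask") {
    u <- unique(as.vector(a))
    bad <- setdiff(u, c(0, 1))
    if (length(bad))
      stop("mask file is not binary; offending values: ",
           paste(utils::head(bad, 5), collapse = ", "))
    voi_mask(a, spacing = sp, origin = org)
  } else {
    pet_image(a, spacing = sp, origin = org, units = units)
  }
}

#' Write a volume, mask or dynamic series to NIfTI
#'
#' Round-trips values, spacing and origin to float precision. Dynamic series
#' are written as one 4D file; write the schedule alongside with
#' [write_schedule_csv()].
#'
#' @param obj a [pet_image()], [voi_mask()] or [dynamic_series()].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_volume <- function(obj, path) {
  if (inherits(obj, "pet_image")) {
    a <- obj$values; sp <- obj$spacing; org <- obj$origin
  } else if (inherits(obj, "voi_mask")) {
    a <- array(as.numeric(obj$values), dim = dim(obj$values))
    sp <- obj$spacing; org <- obj$origin
  } else if (inherits(obj, "dynamic_series")) {
    a <- obj$frames; sp <- obj$spacing; org <- obj$origin
  } else stop("cannot write object of class ", class(obj)[1])
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- if (length(dim(a)) == 4L) c(sp, 1) else sp
  aff <- rbind(cbind(diag(sp), org), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a dynamic series from a 4D NIfTI plus a frame-schedule CSV
#'
#' @param path 4D NIfTI file (x, y, z, t).
#' @param schedule a [frame_schedule()] or path to a schedule CSV
#'   (columns frame_index, start_s, duration_s).
#' @param units units tag, default `"Bq/mL"`.
#' @return a [dynamic_series()].
#' @export
read_dynamic_series <- function(path, schedule, units = "Bq/mL") {
  if (is.character(schedule)) schedule <- read_schedule_csv(schedule)
  img <- RNifti::readNifti(path)
  a <- strip_nifti_attrs(img)
  if (length(dim(a)) != 4L) stop("expected a 4D NIfTI volume")
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  dynamic_series(a, schedule, spacing = sp, origin = org, units = units)
}

## plain numeric array from an RNifti image (drops header attributes)
strip_nifti_attrs <- function(img) {
  a <- as.array(img)
  array(as.vector(a), dim = dim(a))
}

## shared grid construction for centre-aligned isotropic resampling:
## output extent covers the input's physical (edge-to-edge) extent and the
## world-coordinate centres of the two grids coincide
isotropic_target_grid <- function(dims, spacing, origin, target) {
  extent <- dims * spacing
  n_out <- pmax(2L, as.integer(ceiling(extent / target - 1e-9)))
  centre <- origin + (dims - 1) / 2 * spacing
  origin_out <- centre - (n_out - 1) / 2 * target
  list(dims = n_out, origin = origin_out)
}

## trilinear interpolation of `vol` at the voxel centres of the target grid,
## with edge clamping outside the input support
trilinear_resample_array <- function(vol, spacing, origin, target_dims,
                                     target_spacing, target_origin) {
  d <- dim(vol)
  if (any(d < 2L)) stop("degenerate single-voxel axis; cannot interpolate")
  ci <- lapply(1:3, function(ax) {
    world <- target_origin[ax] + (seq_len(target_dims[ax]) - 1) *
      target_spacing[ax]
    idx <- (world - origin[ax]) / spacing[ax] + 1
    pmin(pmax(idx, 1), d[ax])                     # edge clamp
  })
  i0 <- lapply(1:3, function(ax) pmin(pmax(floor(ci[[ax]]), 1), d[ax] - 1))
  fr <- lapply(1:3, function(ax) ci[[ax]] - i0[[ax]])
  out <- array(0, dim = target_dims)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    wx <- if (a == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (b == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (cc == 0) 1 - fr[[3]] else fr[[3]]
    w <- outer(outer(wx, wy), wz)
    out <- out + w * vol[i0[[1]] + a, i0[[2]] + b, i0[[3]] + cc,
                         drop = FALSE]
  }
  out
}

#' Resample an image trilinearly to an isotropic grid
#'
#' Centre-aligned resampling: the output grid is isotropic at
#' `target_spacing_mm`, its physical extent covers the input's, and the
#' world-coordinate centres of the input and output grids coincide. Values
#' are trilinearly interpolated; samples falling outside the input support
#' take the nearest-edge value (no zeros are injected next to the VOI).
#'
#' @param image a [pet_image()].
#' @param target_spacing_mm positive scalar, mm.
#' @return a [pet_image()] on the isotropic grid.
#' @export
resample_isotropic <- function(image, target_spacing_mm) {
  stopifnot(inherits(image, "pet_image"))
  if (target_spacing_mm <= 0) stop("target spacing must be positive")
  d <- dim(image$values)
  g <- isotropic_target_grid(d, image$spacing, image$origin,
                             target_spacing_mm)
  vals <- trilinear_resample_array(image$values, image$spacing, image$origin,
                                   g$dims, rep(target_spacing_mm, 3),
                                   g$origin)
  pet_image(vals, rep(target_spacing_mm, 3), g$origin, image$units)
}

#' Resample a binary mask to an isotropic grid
#'
#' The mask is interpolated trilinearly as a real-valued partial-volume
#' field on the same centre-aligned grid as [resample_isotropic()] would
#' produce for its image, then binarised at `threshold` (default 0.5, which
#' approximately preserves volume).
#'
#' @param mask a [voi_mask()].
#' @param target_spacing_mm positive scalar, mm.
#' @param threshold binarisation level in (0, 1).
#' @return a [voi_mask()] on the isotropic grid.
#' @export
resample_mask <- function(mask, target_spacing_mm, threshold = 0.5) {
  stopifnot(inherits(mask, "voi_mask"))
  if (target_spacing_mm <= 0) stop("target spacing must be positive")
  d <- dim(mask$values)
  g <- isotropic_target_grid(d, mask$spacing, mask$origin, target_spacing_mm)
  field <- trilinear_resample_array(
    array(as.numeric(mask$values), dim = d), mask$spacing, mask$origin,
    g$dims, rep(target_spacing_mm, 3), g$origin)
  bin <- field >= threshold
  if (!any(bin)) stop("mask empty after resampling/thresholding")
  voi_mask(bin, rep(target_spacing_mm, 3), g$origin)
}

#' Resample every frame of a dynamic series to an isotropic grid
#'
#' Frames are interpolated independently and then stacked (equivalently,
#' stacking first and resampling frame-by-frame gives the same 4D volume).
#'
#' @param series a [dynamic_series()].
#' @param target_spacing_mm positive scalar, mm.
#' @return a [dynamic_series()] on the isotropic grid.
#' @export
resample_series <- function(series, target_spacing_mm) {
  stopifnot(inherits(series, "dynamic_series"))
  nt <- n_frames(series$schedule)
  frames <- lapply(seq_len(nt), function(t)
    resample_isotropic(get_frame(series, t), target_spacing_mm))
  dynamic_series(lapply(frames, `[[`, "values"), series$schedule,
                 spacing = rep(target_spacing_mm, 3),
                 origin = frames[[1]]$origin, units = series$units)
}
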