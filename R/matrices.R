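#' The 13 unique 3D neighbour directions
#'
#' Offsets to the 26 directly neighbouring voxels come in 13 antipodal
#' pairs; one representative per pair (the lexicographically positive one)
#' is returned. Texture matrices scan each direction and, for the symmetric
#' spatial matrices, its negation, achieving rotational invariance when the
#' 13 per-direction matrices are merged.
#'
#' @return integer 13 x 3 matrix of (dx, dy, dz) offsets.
#' @export
neighbour_directions_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- apply(g, 1, function(d) {
    nz <- which(d != 0)[1]
    d[nz] > 0
  })
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

## place per-voxel grey levels back on the mask grid (0 outside the VOI)
levels_on_grid <- function(dvoi, mask) {
  stopifnot(inherits(mask, "voi_mask"))
  lv <- if (inherits(dvoi, "discretised_voi")) dvoi$levels else
    as.integer(dvoi)
  idx <- which(mask$values)
  if (length(lv) != length(idx))
    stop("discretised VOI length (", length(lv),
         ") does not match mask voxel count (", length(idx), ")")
  arr <- array(0L, dim = dim(mask$values))
  arr[idx] <- lv
  arr
}

## sub-array index ranges for a shift by direction d (empty when the axis is
## too short to shift)
shift_ranges <- function(dims, d) {
  lapply(1:3, function(ax) {
    if (d[ax] >= 0) seq_len(dims[ax] - d[ax])
    else seq_len(dims[ax] + d[ax]) - d[ax]
  })
}

#' Build the merged 3D grey level co-occurrence matrix
#'
#' Counts pairs of grey levels of in-mask voxels at Chebyshev distance 1,
#' over all 13 directions and both orientations per direction (the matrix is
#' symmetric by construction), merged into a single Ng x Ng matrix. No
#' distance weighting is applied.
#'
#' @param dvoi a [apply_fixed_width()] result aligned with `mask` (or a bare
#'   integer level vector in [extract_voi_values()] order).
#' @param mask a [voi_mask()].
#' @param ng matrix dimension; default the highest occupied level.
#' @return object of class `cooccurrence_matrix`: integer `counts` (Ng x Ng,
#'   symmetric), `symmetric = TRUE`.
#' @export
build_glcm_3d <- function(dvoi, mask, ng = NULL) {
  arr <- levels_on_grid(dvoi, mask)
  if (is.null(ng)) ng <- max(arr)
  if (ng < 1) stop("need at least one grey level")
  d <- dim(arr)
  counts <- matrix(0, ng, ng)
  dirs <- neighbour_directions_3d()
  for (r in seq_len(nrow(dirs))) {
    dd <- dirs[r, ]
    rs <- shift_ranges(d, dd)
    A <- arr[rs[[1]], rs[[2]], rs[[3]], drop = FALSE]
    B <- arr[rs[[1]] + dd[1], rs[[2]] + dd[2], rs[[3]] + dd[3],
             drop = FALSE]
    ok <- A > 0L & B > 0L
    if (!any(ok)) next
    tab <- tabulate((A[ok] - 1L) * ng + B[ok], nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  counts <- counts + t(counts)   # both orientations per angle
  structure(list(counts = counts, symmetric = TRUE),
            class = "cooccurrence_matrix")
}

## maximal-run scan along direction d over the whole grid; returns a
## two-column matrix (level, length) of in-mask runs
scan_runs_direction <- function(arr, d) {
  dims <- dim(arr)
  n <- prod(dims)
  ii <- slice.index(arr, 1); jj <- slice.index(arr, 2)
  kk <- slice.index(arr, 3)
  ## steps available backwards along -d before leaving the grid
  t <- rep(.Machine$integer.max, n)
  co <- list(as.vector(ii), as.vector(jj), as.vector(kk))
  for (ax in 1:3) {
    if (d[ax] == 1) t <- pmin(t, co[[ax]] - 1L)
    else if (d[ax] == -1) t <- pmin(t, dims[ax] - co[[ax]])
  }
  anchor <- vapply(1:3, function(ax) co[[ax]] - t * d[ax], numeric(n))
  key <- (anchor[, 1] - 1) + (anchor[, 2] - 1) * dims[1] +
    (anchor[, 3] - 1) * dims[1] * dims[2]
  o <- order(key, t)
  v <- as.vector(arr)[o]; kg <- key[o]
  newrun <- c(TRUE, kg[-1] != kg[-n] | v[-1] != v[-n])
  run_id <- cumsum(newrun)
  len <- tabulate(run_id)
  lvl <- v[newrun]
  cbind(level = lvl[lvl > 0L], length = len[lvl > 0L])
}

#' Build the merged 3D grey level run length matrix
#'
#' Maximal runs of equal grey level along each of the 13 directions,
#' accumulated into one Ng x Lmax matrix. Out-of-mask voxels break runs.
#' The weighted total `sum(counts * length)` equals `Nvoxels * 13`.
#'
#' @inheritParams build_glcm_3d
#' @return object of class `runlength_matrix` with `counts` (Ng x Lmax) and
#'   `n_directions = 13`.
#' @export
build_glrlm_3d <- function(dvoi, mask, ng = NULL) {
  arr <- levels_on_grid(dvoi, mask)
  if (is.null(ng)) ng <- max(arr)
  dirs <- neighbour_directions_3d()
  runs <- do.call(rbind, lapply(seq_len(nrow(dirs)), function(r)
    scan_runs_direction(arr, dirs[r, ])))
  lmax <- max(runs[, "length"])
  counts <- matrix(0, ng, lmax)
  for (rr in seq_len(nrow(runs)))
    counts[runs[rr, 1], runs[rr, 2]] <- counts[runs[rr, 1], runs[rr, 2]] + 1
  structure(list(counts = counts, n_directions = nrow(dirs)),
            class = "runlength_matrix")
}

#' Build the grey level size zone matrix
#'
#' 26-connected zones of equal grey level inside the VOI, tallied by
#' (level, zone size). Zone sizes sum to the VOI voxel count.
#'
#' @inheritParams build_glcm_3d
#' @return object of class `sizezone_matrix` with `counts` (Ng x Zmax).
#' @export
build_glszm <- function(dvoi, mask, ng = NULL) {
  arr <- levels_on_grid(dvoi, mask)
  if (is.null(ng)) ng <- max(arr)
  dims <- dim(arr)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  visited <- array(FALSE, dims)
  zones <- list()
  for (start in which(arr > 0L & !visited)) {
    if (visited[start]) next
    lvl <- arr[start]
    stack <- start
    visited[start] <- TRUE
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      cc <- arrayInd(cur, dims)
      for (m in seq_len(nrow(offs))) {
        nb <- cc + offs[m, ]
        if (any(nb < 1L) || any(nb > dims)) next
        li <- nb[1] + (nb[2] - 1L) * dims[1] + (nb[3] - 1L) * dims[1] * dims[2]
        if (!visited[li] && arr[li] == lvl) {
          visited[li] <- TRUE
          stack <- c(stack, li)
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(lvl, size)
  }
  zm <- do.call(rbind, zones)
  counts <- matrix(0, ng, max(zm[, 2]))
  for (rr in seq_len(nrow(zm)))
    counts[zm[rr, 1], zm[rr, 2]] <- counts[zm[rr, 1], zm[rr, 2]] + 1
  structure(list(counts = counts), class = "sizezone_matrix")
}

#' Build the neighbouring grey tone difference matrix
#'
#' For each occupied grey level i: the number of VOI voxels with that level
#' (among voxels having at least one in-mask neighbour) and the summed
#' absolute difference between i and the mean level of each such voxel's
#' in-mask 26-neighbourhood (the centre voxel excluded).
#'
#' @inheritParams build_glcm_3d
#' @return object of class `ngtdm_matrix`: vectors `n_i`, `s_i` indexed by
#'   level 1..Ng, and `n_vp` (number of contributing voxels).
#' @export
build_ngtdm <- function(dvoi, mask, ng = NULL) {
  arr <- levels_on_grid(dvoi, mask)
  if (is.null(ng)) ng <- max(arr)
  d <- dim(arr)
  inmask <- arr > 0L
  sumN <- array(0, d); cntN <- array(0, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (m in seq_len(nrow(offs))) {
    dd <- offs[m, ]
    rs <- shift_ranges(d, dd)
    tgt <- lapply(1:3, function(ax) rs[[ax]] + dd[ax])
    sumN[rs[[1]], rs[[2]], rs[[3]]] <-
      sumN[rs[[1]], rs[[2]], rs[[3]], drop = FALSE] +
      arr[tgt[[1]], tgt[[2]], tgt[[3]], drop = FALSE] *
      inmask[tgt[[1]], tgt[[2]], tgt[[3]], drop = FALSE]
    cntN[rs[[1]], rs[[2]], rs[[3]]] <-
      cntN[rs[[1]], rs[[2]], rs[[3]], drop = FALSE] +
      inmask[tgt[[1]], tgt[[2]], tgt[[3]], drop = FALSE]
  }
  sel <- inmask & cntN >= 1
  lv <- arr[sel]
  diffs <- abs(lv - sumN[sel] / cntN[sel])
  n_i <- tabulate(lv, nbins = ng)
  s_i <- vapply(seq_len(ng), function(g) sum(diffs[lv == g]), numeric(1))
  structure(list(n_i = n_i, s_i = s_i, n_vp = sum(sel)),
            class = "ngtdm_matrix")
}

#' Build the causal temporal grey level co-occurrence matrix
#'
#' For every VOI voxel and every frame transition t -> t+1, increments cell
#' (level at t, level at t+1). Only the forward temporal direction
#' (0; 0; 0; 1) is scanned — causality makes the reverse pair meaningless —
#' so the matrix is asymmetric by construction. All transitions are pooled
#' into one matrix of dimension `global_ng`, the shared grey-level count
#' across frames. Total count is `Nvoxels * (T - 1)`.
#'
#' @param frame_levels list of per-frame [apply_fixed_width()] results (or
#'   bare level vectors), voxel-aligned across frames; typically the
#'   `frames` element of [discretise_frames()].
#' @param global_ng shared matrix dimension (max Ng over frames).
#' @return object of class `cooccurrence_matrix` with `symmetric = FALSE`.
#' @export
build_temporal_glcm <- function(frame_levels, global_ng) {
  lv <- lapply(frame_levels, function(f)
    if (inherits(f, "discretised_voi")) f$levels else as.integer(f))
  if (length(lv) < 2L) stop("need at least 2 frames")
  nv <- unique(vapply(lv, length, 1L))
  if (length(nv) != 1L)
    stop("frames have mismatched VOI voxel sets: counts ",
         paste(unique(vapply(lv, length, 1L)), collapse = ", "))
  ng <- as.integer(global_ng)
  counts <- matrix(0, ng, ng)
  for (t in seq_len(length(lv) - 1L)) {
    tab <- tabulate((lv[[t]] - 1L) * ng + lv[[t + 1L]], nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  structure(list(counts = counts, symmetric = FALSE),
            class = "cooccurrence_matrix")
}

#' Build the temporal grey level run length matrix
#'
#' Maximal runs of constant grey level along each voxel's time course,
#' tallied by (level, run length); run lengths range 1..T and the weighted
#' total `sum(counts * length)` equals `Nvoxels * T`.
#'
#' @inheritParams build_temporal_glcm
#' @return object of class `runlength_matrix` with Ng x T `counts` and
#'   `n_directions = 1`.
#' @export
build_temporal_glrlm <- function(frame_levels, global_ng) {
  lv <- lapply(frame_levels, function(f)
    if (inherits(f, "discretised_voi")) f$levels else as.integer(f))
  if (length(lv) < 2L) stop("need at least 2 frames")
  nv <- unique(vapply(lv, length, 1L))
  if (length(nv) != 1L) stop("frames have mismatched VOI voxel sets")
  nt <- length(lv)
  ng <- as.integer(global_ng)
  ## column = voxel time course; runs never cross voxel boundaries
  M <- matrix(unlist(lv), nrow = nv, ncol = nt)
  v <- as.vector(t(M))
  grp <- rep(seq_len(nv), each = nt)
  n <- length(v)
  newrun <- c(TRUE, grp[-1] != grp[-n] | v[-1] != v[-n])
  run_id <- cumsum(newrun)
  len <- tabulate(run_id)
  lvl <- v[newrun]
  counts <- matrix(0, ng, nt)
  for (rr in seq_along(len))
    counts[lvl[rr], len[rr]] <- counts[lvl[rr], len[rr]] + 1
  structure(list(counts = counts, n_directions = 1L),
            class = "runlength_matrix")
}
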