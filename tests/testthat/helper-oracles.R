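# Independent brute-force oracles for every matrix builder and for trilinear
# interpolation. These deliberately use the slowest, most literal
# formulation (explicit loops over voxels, offsets and time points) so they
# share no code path with the package implementations they check.

all_offsets_26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# random small discretised VOI on a grid; returns mask, level array and the
# level vector in extract_voi_values order
random_voi <- function(max_dim = 6, ng = 4) {
  d <- sample(3:max_dim, 3, replace = TRUE)
  m <- array(stats::runif(prod(d)) < 0.7, dim = d)
  if (!any(m)) m[sample(prod(d), 1)] <- TRUE
  lv <- array(0L, d)
  lv[m] <- sample.int(ng, sum(m), replace = TRUE)
  list(mask = voi_mask(m), arr = lv, levels = lv[which(m)], ng = ng)
}

oracle_glcm <- function(arr, ng) {
  d <- dim(arr)
  M <- matrix(0, ng, ng)
  offs <- all_offsets_26()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- arr[i, j, k]
    if (a == 0L) next
    for (r in seq_len(nrow(offs))) {
      p <- c(i, j, k) + offs[r, ]
      if (any(p < 1) || any(p > d)) next
      b <- arr[p[1], p[2], p[3]]
      if (b > 0L) M[a, b] <- M[a, b] + 1
    }
  }
  M
}

oracle_glrlm <- function(arr, ng) {
  d <- dim(arr)
  dirs <- neighbour_directions_3d()
  runs <- list()
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (r in seq_len(nrow(dirs))) {
    dd <- dirs[r, ]
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      v <- c(i, j, k)
      a <- arr[i, j, k]
      if (a == 0L) next
      prev <- v - dd
      if (inb(prev) && arr[prev[1], prev[2], prev[3]] == a) next  # not a start
      len <- 1L
      nxt <- v + dd
      while (inb(nxt) && arr[nxt[1], nxt[2], nxt[3]] == a) {
        len <- len + 1L
        nxt <- nxt + dd
      }
      runs[[length(runs) + 1L]] <- c(a, len)
    }
  }
  rm <- do.call(rbind, runs)
  M <- matrix(0, ng, max(rm[, 2]))
  for (q in seq_len(nrow(rm))) M[rm[q, 1], rm[q, 2]] <- M[rm[q, 1], rm[q, 2]] + 1
  M
}

oracle_glszm <- function(arr, ng) {
  d <- dim(arr)
  offs <- all_offsets_26()
  lab <- array(0L, d)
  nextlab <- 0L
  sizes <- integer(0); lvls <- integer(0)
  for (s in which(arr > 0L)) {
    if (lab[s] > 0L) next
    nextlab <- nextlab + 1L
    members <- s
    lab[s] <- nextlab
    frontier <- s
    while (length(frontier)) {
      newf <- integer(0)
      for (f in frontier) {
        cc <- arrayInd(f, d)
        for (r in seq_len(nrow(offs))) {
          p <- cc + offs[r, ]
          if (any(p < 1) || any(p > d)) next
          li <- p[1] + (p[2] - 1L) * d[1] + (p[3] - 1L) * d[1] * d[2]
          if (lab[li] == 0L && arr[li] == arr[s]) {
            lab[li] <- nextlab
            newf <- c(newf, li)
          }
        }
      }
      members <- c(members, newf)
      frontier <- newf
    }
    sizes <- c(sizes, length(members))
    lvls <- c(lvls, arr[s])
  }
  M <- matrix(0, ng, max(sizes))
  for (q in seq_along(sizes)) M[lvls[q], sizes[q]] <- M[lvls[q], sizes[q]] + 1
  M
}

oracle_ngtdm <- function(arr, ng) {
  d <- dim(arr)
  offs <- all_offsets_26()
  n_i <- numeric(ng); s_i <- numeric(ng); nvp <- 0L
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- arr[i, j, k]
    if (a == 0L) next
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      p <- c(i, j, k) + offs[r, ]
      if (any(p < 1) || any(p > d)) next
      b <- arr[p[1], p[2], p[3]]
      if (b > 0L) nb <- c(nb, b)
    }
    if (length(nb) == 0L) next
    nvp <- nvp + 1L
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  list(n_i = n_i, s_i = s_i, n_vp = nvp)
}

oracle_temporal_glcm <- function(level_mat, ng) {
  # level_mat: voxels x frames
  M <- matrix(0, ng, ng)
  for (v in seq_len(nrow(level_mat)))
    for (t in seq_len(ncol(level_mat) - 1L)) {
      a <- level_mat[v, t]; b <- level_mat[v, t + 1L]
      M[a, b] <- M[a, b] + 1
    }
  M
}

oracle_temporal_glrlm <- function(level_mat, ng) {
  nt <- ncol(level_mat)
  M <- matrix(0, ng, nt)
  for (v in seq_len(nrow(level_mat))) {
    r <- rle(level_mat[v, ])
    for (q in seq_along(r$lengths))
      M[r$values[q], r$lengths[q]] <- M[r$values[q], r$lengths[q]] + 1
  }
  M
}

# direct 8-corner trilinear evaluation of vol at one continuous (1-based)
# index, with edge clamping
oracle_trilinear_at <- function(vol, ci) {
  d <- dim(vol)
  ci <- pmin(pmax(ci, 1), d)
  i0 <- pmin(pmax(floor(ci), 1), d - 1)
  f <- ci - i0
  val <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    w <- (if (a) f[1] else 1 - f[1]) * (if (b) f[2] else 1 - f[2]) *
      (if (cc) f[3] else 1 - f[3])
    val <- val + w * vol[i0[1] + a, i0[2] + b, i0[3] + cc]
  }
  val
}

# small constant-level cuboid VOI helper
cuboid_voi <- function(d, level = 1L) {
  m <- array(TRUE, dim = d)
  list(mask = voi_mask(m), arr = array(as.integer(level), d),
       levels = rep(as.integer(level), prod(d)))
}

# 90 degree rotation about the z axis (x,y,z) -> (y, -x, z)
rot90_z <- function(arr) {
  out <- aperm(arr, c(2, 1, 3))
  out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
}
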