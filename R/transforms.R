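# Rigid-body transforms and image resampling.
#
# Convention: a parameter 6-vector p = (roll, pitch, yaw, dS, dL, dP) with
# rotations in degrees about the world z, x and y axes and translations in
# mm along z, x and y.  The rigid map acts about a rotation centre
# (default: the grid centre in world mm).  All resampling goes through a
# single out->in coordinate map so that chains of transforms cost exactly
# one interpolation per voxel.

#' Build the 4x4 world-space affine of a rigid parameter vector
#'
#' @param params Length-6 vector (roll, pitch, yaw in degrees; dS, dL, dP
#'   in mm).
#' @param center World-mm rotation centre (default origin).
#' @return 4x4 affine matrix with orthonormal rotation part (det +1).
#' @export
rigid_affine <- function(params, center = c(0, 0, 0)) {
  stopifnot(length(params) == 6L)
  a <- params[1:3] * pi / 180  # roll(z), pitch(x), yaw(y)
  cz <- cos(a[1]); sz <- sin(a[1])
  cx <- cos(a[2]); sx <- sin(a[2])
  cy <- cos(a[3]); sy <- sin(a[3])
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  R <- Rz %*% Rx %*% Ry
  t_xyz <- c(params[5], params[6], params[4])  # dL->x, dP->y, dS->z
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- center - R %*% center + t_xyz
  A
}

grid_center_world <- function(grid) {
  grid_voxel_to_world(grid, (grid$dims - 1) / 2)
}

# 1D interpolation weights for a fractional offset f in [0,1) relative to
# the integer floor sample, for the named kernel.  Returns the integer tap
# offsets and a (taps x length(f)) weight matrix.
kernel_taps <- function(kernel) {
  switch(kernel,
         nearest = 0L, trilinear = 0:1, cubic = -1:2,
         wsinc5 = -4:5, wsinc9 = -8:9,
         stop2("unknown interpolation kernel '%s'", kernel))
}

kernel_weights <- function(kernel, f) {
  taps <- kernel_taps(kernel)
  if (kernel == "nearest")
    return(matrix(1, nrow = 1, ncol = length(f)))
  if (kernel == "trilinear")
    return(rbind(1 - f, f))
  if (kernel == "cubic") {
    # Keys cubic convolution, a = -0.5
    w <- vapply(taps, function(m) {
      s <- abs(f - m)
      ifelse(s < 1, 1.5 * s^3 - 2.5 * s^2 + 1,
             ifelse(s < 2, -0.5 * s^3 + 2.5 * s^2 - 4 * s + 2, 0))
    }, numeric(length(f)))
    return(t(matrix(w, nrow = length(f))))
  }
  # Hann-windowed sinc of half-width h (5 or 9 voxels)
  h <- if (kernel == "wsinc5") 5 else 9
  w <- vapply(taps, function(m) {
    s <- f - m
    v <- ifelse(abs(s) < 1e-12, 1, sin(pi * s) / (pi * s))
    win <- ifelse(abs(s) <= h, 0.5 * (1 + cos(pi * s / h)), 0)
    v * win
  }, numeric(length(f)))
  w <- t(matrix(w, nrow = length(f)))
  sweep(w, 2, colSums(w), "/")  # renormalize so constants are preserved
}

# Gather arr values at 0-based integer voxel coords; outside -> 0.
gather3 <- function(arr, d, i, j, k) {
  ok <- i >= 0L & i < d[1] & j >= 0L & j < d[2] & k >= 0L & k < d[3]
  out <- numeric(length(i))
  idx <- 1L + i[ok] + d[1] * (j[ok] + d[2] * k[ok])
  out[ok] <- arr[idx]
  out
}

# Interpolate a 3D array at fractional 0-based voxel coords (3 x M matrix).
interp3 <- function(arr, pts, kernel = "trilinear") {
  d <- dim(arr)
  if (kernel == "nearest") {
    return(gather3(arr, d, as.integer(round(pts[1, ])),
                   as.integer(round(pts[2, ])),
                   as.integer(round(pts[3, ]))))
  }
  if (kernel == "trilinear") {
    # fast path: one base index shared by the 8 taps, clamped neighbours
    # (a clamped neighbour always carries zero weight), outside -> 0
    i0 <- floor(pts[1, ]); j0 <- floor(pts[2, ]); k0 <- floor(pts[3, ])
    fx <- pts[1, ] - i0; fy <- pts[2, ] - j0; fz <- pts[3, ] - k0
    ok <- i0 >= 0 & (i0 + (fx > 0)) <= d[1] - 1 &
          j0 >= 0 & (j0 + (fy > 0)) <= d[2] - 1 &
          k0 >= 0 & (k0 + (fz > 0)) <= d[3] - 1
    i0 <- pmin(pmax(i0, 0), d[1] - 1)
    j0 <- pmin(pmax(j0, 0), d[2] - 1)
    k0 <- pmin(pmax(k0, 0), d[3] - 1)
    dx <- as.numeric(i0 < d[1] - 1)
    dy <- as.numeric(j0 < d[2] - 1) * d[1]
    dz <- as.numeric(k0 < d[3] - 1) * d[1] * d[2]
    b <- 1 + i0 + d[1] * (j0 + d[2] * k0)
    gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
    v <- gz * (gy * (gx * arr[b] + fx * arr[b + dx]) +
               fy * (gx * arr[b + dy] + fx * arr[b + dx + dy])) +
         fz * (gy * (gx * arr[b + dz] + fx * arr[b + dx + dz]) +
               fy * (gx * arr[b + dy + dz] + fx * arr[b + dx + dy + dz]))
    return(v * ok)
  }
  i0 <- floor(pts)
  f <- pts - i0
  i0 <- array(as.integer(i0), dim = dim(i0))
  taps <- kernel_taps(kernel)
  wx <- kernel_weights(kernel, f[1, ])
  wy <- kernel_weights(kernel, f[2, ])
  wz <- kernel_weights(kernel, f[3, ])
  out <- numeric(ncol(pts))
  for (a in seq_along(taps)) {
    wza <- wz[a, ]
    if (all(wza == 0)) next
    kk <- i0[3, ] + taps[a]
    for (b in seq_along(taps)) {
      wyb <- wy[b, ] * wza
      jj <- i0[2, ] + taps[b]
      for (cc in seq_along(taps)) {
        w <- wx[cc, ] * wyb
        out <- out + w * gather3(arr, d, i0[1, ] + taps[cc], jj, kk)
      }
    }
  }
  out
}

# Cached 0-based voxel index grid (3 x prod(dims)) for an output grid.
voxel_grid_points <- function(dims) {
  rbind(
    rep.int(0:(dims[1] - 1), dims[2] * dims[3]),
    rep.int(rep(0:(dims[2] - 1), each = dims[1]), dims[3]),
    rep(0:(dims[3] - 1), each = dims[1] * dims[2]))
}

#' Resample a 3D volume through a world-space coordinate map
#'
#' Samples the input at `world_map %*% x` for every output world location
#' `x`: `world_map` maps output world coordinates to input world
#' coordinates.  Composing several transforms into one `world_map` before
#' calling keeps the whole chain down to a single interpolation.
#'
#' @param arr 3D numeric array on `in_grid`.
#' @param in_grid,out_grid [make_grid()] geometries.
#' @param world_map 4x4 affine, output world mm -> input world mm.
#' @param kernel One of `nearest`, `trilinear`, `cubic`, `wsinc5`, `wsinc9`.
#' @return 3D array on `out_grid` (outside-volume samples are 0).
#' @export
resample_volume <- function(arr, in_grid, out_grid = in_grid,
                            world_map = diag(4), kernel = "trilinear") {
  vmap <- solve(in_grid$affine) %*% world_map %*% out_grid$affine
  pts <- vmap[1:3, 1:3] %*% voxel_grid_points(out_grid$dims) + vmap[1:3, 4]
  array(interp3(arr, pts, kernel), dim = out_grid$dims)
}

#' Apply a rigid motion to a 4D series (used to inject phantom motion)
#'
#' Moves the imaged object by the rigid transform of `params` about the
#' grid centre: a feature at world location x appears at T(x) afterwards.
#' The inverse operation (motion correction) is resampling through
#' `rigid_affine(params)` itself.
#'
#' @param vol A [volume4d()].
#' @param params Either a length-6 vector applied to all volumes or an
#'   n_volumes x 6 matrix.
#' @param kernel Interpolation kernel.
#' @return Transformed `volume4d`.
#' @export
apply_rigid_motion <- function(vol, params, kernel = "trilinear") {
  if (is.null(dim(params)))
    params <- matrix(params, nrow = n_volumes(vol), ncol = 6, byrow = TRUE)
  ctr <- grid_center_world(vol$grid)
  out <- vol$data
  for (t in seq_len(n_volumes(vol))) {
    if (max(abs(params[t, ])) == 0) next
    A <- solve(rigid_affine(params[t, ], ctr))
    out[, , , t] <- resample_volume(vol$data[, , , t], vol$grid,
                                    vol$grid, A, kernel)
  }
  vol_with(vol, out)
}
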