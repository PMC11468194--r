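# Data-transforming processing blocks: tcat trimming, outlier counting,
# pre-steady-state detection, slice-timing correction, rigid motion
# estimation/correction with single-step resampling, blurring, automasking,
# percent-signal scaling, simple despiking and multi-echo optimal
# combination.

# Threshold multiplier for the robust temporal outlier test: two-sided
# Gaussian tail probability 0.001.
OUTLIER_K <- qnorm(1 - 0.001 / 2)

#' Remove initial volumes from each run
#'
#' Drops the first `n` time points of every run (the tcat step), typically
#' to discard pre-steady-state magnetisation volumes.
#'
#' @param vol A [volume4d()].
#' @param n Number of leading volumes to remove per run (`0 <= n <`
#'   shortest run length).
#' @return Trimmed `volume4d`; TR and slice timing unchanged.
#' @export
remove_initial_volumes <- function(vol, n) {
  if (!is_count(n)) stop2("n must be a non-negative integer")
  if (n >= min(vol$runs))
    stop2("cannot remove %d volumes from a run of length %d", n, min(vol$runs))
  if (n == 0L) return(vol)
  keep <- unlist(lapply(run_index(vol$runs), function(ix) ix[-seq_len(n)]))
  vol_with(vol, vol$data[, , , keep, drop = FALSE], runs = vol$runs - as.integer(n))
}

# Residuals of the per-run baseline polynomial detrend, as a time x voxel
# matrix (used by the outlier counter, despiking and QC variance checks).
detrend_residuals <- function(Y, runs, tr, polort = NULL) {
  X <- baseline_regressors(runs, tr, polort %||% "auto")$X
  for (ix in run_index(runs)) {
    Xr <- X[ix, colSums(abs(X[ix, , drop = FALSE])) > 0, drop = FALSE]
    fit <- qr(Xr)
    Y[ix, ] <- Y[ix, , drop = FALSE] -
      Xr %*% qr.coef(fit, Y[ix, , drop = FALSE])
  }
  Y
}

col_medians <- function(M) apply(M, 2, median)

#' Per-volume temporal outlier fraction
#'
#' For each volume, the fraction of in-mask voxels whose baseline-detrended
#' residual exceeds `k * MADN` of that voxel's residual series, where MADN
#' is the normalized median absolute deviation and `k` is the two-sided
#' Gaussian 0.001 quantile (about 3.29).
#'
#' @param vol A [volume4d()] with at least 5 volumes.
#' @param mask Logical 3D array on the same grid.
#' @return Numeric vector of fractions in `[0, 1]`, one per volume.
#' @export
temporal_outlier_fraction <- function(vol, mask) {
  if (n_volumes(vol) < 5L) stop2("need at least 5 volumes to count outliers")
  maskv <- as.vector(mask)
  if (!any(maskv)) stop2("empty mask")
  R <- detrend_residuals(vol_as_tv(vol)[, maskv, drop = FALSE],
                         vol$runs, vol$tr)
  madn_v <- 1.4826 * col_medians(abs(R))
  thr <- OUTLIER_K * madn_v
  rowMeans(sweep(abs(R), 2, thr, ">") & rep(thr > 0, each = nrow(R)))
}

#' Flag leading pre-steady-state volumes
#'
#' Counts how many leading volumes have an in-mask mean intensity more than
#' `2 * MADN` above the run's robust (median) level, where both statistics
#' are computed from the last 80 percent of volumes.  T1 saturation makes
#' the first few volumes of an EPI run systematically brighter, so a
#' positive count here that exceeds the number of removed volumes is a
#' warning sign.
#'
#' @inheritParams temporal_outlier_fraction
#' @return Integer count of flagged leading volumes (0 when none).
#' @export
detect_pre_steady_state <- function(vol, mask) {
  maskv <- as.vector(mask)
  if (!any(maskv)) stop2("empty mask")
  m <- rowMeans(vol_as_tv(vol)[, maskv, drop = FALSE])
  n <- length(m)
  ref <- m[max(1, ceiling(0.2 * n) + 1):n]
  thr <- median(ref) + 2 * madn(ref)
  flagged <- 0L
  for (t in seq_len(n)) {
    if (m[t] > thr) flagged <- t else break
  }
  flagged
}

#' Slice-timing correction
#'
#' Resamples each z-slice's time series to a common temporal origin.  The
#' series is shifted by `(align_to - slice_time) / TR` samples using the
#' requested interpolation kernel, with edge-hold extrapolation at the run
#' boundaries.
#'
#' @param vol A [volume4d()] with slice timing present.
#' @param method `linear`, `cubic` (default) or `wsinc5`/`wsinc9` for
#'   high-order Hann-windowed sinc interpolation.
#' @param align_to Target within-TR time in seconds (default 0).
#' @return Corrected `volume4d` with all slice times set to `align_to`.
#' @export
slice_time_correct <- function(vol, method = "cubic", align_to = 0) {
  if (!length(vol$slice_times)) stop2("volume has no slice timing information")
  method <- match.arg(method, c("linear", "cubic", "wsinc5", "wsinc9"))
  kern <- if (method == "linear") "trilinear" else method
  d <- dim(vol$data)
  out <- vol$data
  for (z in seq_len(d[3])) {
    delta <- (align_to - vol$slice_times[z]) / vol$tr
    if (abs(delta) < 1e-12) next
    sl <- matrix(vol$data[, , z, ], nrow = d[1] * d[2], ncol = d[4])
    for (ix in run_index(vol$runs)) {
      W <- shift_matrix(length(ix), delta, kern)
      sl[, ix] <- sl[, ix, drop = FALSE] %*% t(W)
    }
    out[, , z, ] <- array(sl, dim = c(d[1], d[2], d[4]))
  }
  vol_with(vol, out, slice_times = rep(align_to, d[3]))
}

# n x n matrix performing y_new[i] = y(i + delta) with edge-hold.
shift_matrix <- function(n, delta, kernel) {
  taps <- kernel_taps(kernel)
  base <- floor(delta)
  w <- kernel_weights(kernel, delta - base)[, 1]
  W <- matrix(0, n, n)
  for (a in seq_along(taps)) {
    src <- clamp(seq_len(n) - 1 + base + taps[a], 0, n - 1)
    W[cbind(seq_len(n), src + 1)] <- W[cbind(seq_len(n), src + 1)] + w[a]
  }
  W
}

#' Choose the minimum-outlier reference volume
#'
#' The registration reference is the volume with the fewest temporal
#' outliers, the choice least likely to be motion-corrupted.  Ties break
#' to the earliest index.
#'
#' @inheritParams temporal_outlier_fraction
#' @return 1-based volume index.
#' @export
select_min_outlier_reference <- function(vol, mask) {
  which.min(temporal_outlier_fraction(vol, mask))
}

# mean-pool a 3D array by 2 along each axis (trailing odd slab dropped)
downsample2 <- function(arr) {
  d <- dim(arr) %/% 2L
  if (any(d < 2L)) return(NULL)
  a <- arr[seq_len(2 * d[1]), seq_len(2 * d[2]), seq_len(2 * d[3])]
  o <- seq(1, 2 * d[1], 2)
  a <- (a[o, , ] + a[o + 1, , ]) / 2
  o <- seq(1, 2 * d[2], 2)
  a <- (a[, o, ] + a[, o + 1, ]) / 2
  o <- seq(1, 2 * d[3], 2)
  (a[, , o] + a[, , o + 1]) / 2
}

coarse_grid <- function(grid) {
  d <- grid$dims %/% 2L
  A <- grid$affine
  A2 <- A
  A2[1:3, 1:3] <- A[1:3, 1:3] * 2
  A2[1:3, 4] <- (A %*% c(0.5, 0.5, 0.5, 1))[1:3]
  make_grid(d, grid$voxel_size * 2, affine = A2)
}

#' Estimate rigid-body motion parameters
#'
#' Registers every volume to the reference by minimising the mean squared
#' intensity difference under a 6-parameter rigid transform, using a
#' coarse-to-fine search: a Nelder-Mead solve on a 2x-downsampled grid
#' (warm-started from the previous volume) followed by a full-resolution
#' polish.  Least squares is appropriate here because all volumes share
#' the same EPI contrast.
#'
#' @param vol A [volume4d()] with at least 2 volumes.
#' @param ref_index Reference volume (1-based), e.g. from
#'   [select_min_outlier_reference()].
#' @param pre_blur_mm FWHM of the light Gaussian smoothing applied to both
#'   images before registration (default twice the mean voxel size).
#'   Matching the smoothness of the two sides keeps the least-squares
#'   cost from being dominated by interpolation blur at sharp edges; the
#'   returned parameters still describe the unsmoothed data.
#' @return A [motion_params()] object (reference row all zero).
#' @export
estimate_rigid_motion <- function(vol, ref_index = 1L, pre_blur_mm = NULL) {
  nt <- n_volumes(vol)
  if (nt < 2L) stop2("need at least 2 volumes to estimate motion")
  pre_blur_mm <- pre_blur_mm %||% (2 * mean(vol$grid$voxel_size))
  if (pre_blur_mm > 0) vol <- gaussian_blur(vol, pre_blur_mm)
  ref <- vol$data[, , , ref_index]
  if (max(abs(ref)) == 0) stop2("reference volume is identically zero")
  ctr <- grid_center_world(vol$grid)
  A <- vol$grid$affine
  Ainv <- solve(A)
  cgrid <- coarse_grid(vol$grid)
  cref <- downsample2(ref)
  # Fine-level cost points: voxels with appreciable signal (the empty
  # corners carry no registration information), capped for speed.
  pts_all <- voxel_grid_points(vol$grid$dims)
  sel <- which(abs(as.vector(ref)) > 0.05 * max(abs(ref)))
  if (length(sel) < 500L) sel <- seq_len(ncol(pts_all))
  if (length(sel) > 4000L)
    sel <- sel[seq(1L, length(sel), length.out = 4000L)]
  pts <- pts_all[, sel, drop = FALSE]
  params <- matrix(0, nt, 6)
  # Symmetric objective: both images are sampled through opposite
  # half-transforms, so interpolation smoothing affects the two sides
  # equally and cannot bias the optimum toward the identity.
  obj_pts <- function(p, moving, target) {
    Ma <- Ainv %*% rigid_affine(p / 2, ctr) %*% A
    Mb <- Ainv %*% rigid_affine(-p / 2, ctr) %*% A
    a <- interp3(moving, Ma[1:3, 1:3] %*% pts + Ma[1:3, 4], "trilinear")
    b <- interp3(target, Mb[1:3, 1:3] %*% pts + Mb[1:3, 4], "trilinear")
    mean((a - b)^2)
  }
  obj_coarse <- function(p, moving, target) {
    a <- resample_volume(moving, cgrid, cgrid, rigid_affine(p / 2, ctr),
                         "trilinear")
    b <- resample_volume(target, cgrid, cgrid, rigid_affine(-p / 2, ctr),
                         "trilinear")
    mean((a - b)^2)
  }
  p_prev <- rep(0, 6)
  order_t <- order(abs(seq_len(nt) - ref_index))  # walk outward from ref
  for (t in order_t) {
    if (t == ref_index) next
    moving <- vol$data[, , , t]
    p <- p_prev
    if (!is.null(cref)) {
      fit <- optim(p, obj_coarse, moving = downsample2(moving),
                   target = cref, method = "Nelder-Mead",
                   control = list(maxit = 250, reltol = 1e-6))
      p <- fit$par
    }
    fit <- optim(p, obj_pts, moving = moving, target = ref,
                 method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-6))
    # restarts rebuild the simplex around the current best point
    for (attempt in 1:4) {
      fit <- optim(fit$par, obj_pts, moving = moving, target = ref,
                   method = "Nelder-Mead",
                   control = list(maxit = 600, reltol = 1e-6))
      if (fit$convergence == 0) break
    }
    if (fit$convergence != 0)
      stop2("motion estimation failed to converge at volume %d", t)
    params[t, ] <- fit$par
    p_prev <- fit$par
  }
  motion_params(params, reference_index = ref_index)
}

#' Apply motion correction and alignment transforms in a single resampling
#'
#' Concatenates the per-volume rigid motion transform, the EPI-to-anatomical
#' affine and the anatomical-to-final affine into one coordinate map per
#' volume and resamples through it once, so each voxel is interpolated
#' exactly one time regardless of how many transforms are in the chain.
#' Sequential application would smooth the data at every step.
#'
#' @param vol A [volume4d()].
#' @param mp [motion_params()] for the series, or `NULL` for none.
#' @param epi2anat,anat2final 4x4 world-mm affines (identity by default).
#' @param out_grid Output [make_grid()] (default: input grid).
#' @param kernel Interpolation kernel (`trilinear`, `cubic`, `wsinc5`,
#'   `wsinc9`).
#' @return Resampled `volume4d` on `out_grid`.
#' @export
apply_concatenated_transform <- function(vol, mp = NULL,
                                         epi2anat = diag(4),
                                         anat2final = diag(4),
                                         out_grid = NULL, kernel = "trilinear") {
  out_grid <- out_grid %||% vol$grid
  if (abs(det(epi2anat[1:3, 1:3])) < 1e-12 ||
      abs(det(anat2final[1:3, 1:3])) < 1e-12)
    stop2("alignment affines must be invertible")
  nt <- n_volumes(vol)
  if (!is.null(mp) && nrow(mp) != nt)
    stop2("motion parameter rows (%d) do not match volumes (%d)", nrow(mp), nt)
  ctr <- grid_center_world(vol$grid)
  fixed <- solve(epi2anat) %*% solve(anat2final)
  out <- array(0, dim = c(out_grid$dims, nt))
  for (t in seq_len(nt)) {
    M <- if (is.null(mp)) diag(4) else rigid_affine(mp[t, ], ctr)
    out[, , , t] <- resample_volume(vol$data[, , , t], vol$grid, out_grid,
                                    M %*% fixed, kernel)
  }
  volume4d(out, grid = out_grid, tr = vol$tr,
           slice_times = numeric(0), units = vol$units, runs = vol$runs)
}

#' Default isotropic output grid
#'
#' The default final grid is isotropic at the input EPI's minimum voxel
#' dimension truncated to one decimal mm, covering the same field of view.
#'
#' @param grid Input [make_grid()].
#' @return A new isotropic `grid3d`.
#' @export
default_output_grid <- function(grid) {
  dx <- floor(min(grid$voxel_size) * 10) / 10
  extent <- grid$voxel_size * grid$dims
  dims <- pmax(1L, as.integer(ceiling(extent / dx)))
  A <- diag(4)
  A[cbind(1:3, 1:3)] <- dx
  # keep the old grid centre fixed
  old_ctr <- grid_center_world(grid)
  A[1:3, 4] <- old_ctr - dx * (dims - 1) / 2
  make_grid(dims, rep(dx, 3), affine = A)
}

# 1D reflective-boundary Gaussian convolution matrix (rows and columns sum
# to 1, so total image intensity is conserved).
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  h <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  W <- matrix(0, n, n)
  for (a in seq(-h, h)) {
    src <- seq_len(n) - 1 + a
    src <- ifelse(src < 0, -1 - src, ifelse(src >= n, 2 * n - 1 - src, src))
    src <- clamp(src, 0, n - 1)
    ind <- cbind(seq_len(n), src + 1)
    W[ind] <- W[ind] + k[a + h + 1]
  }
  W
}

apply_axis <- function(arr, axis, W) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- W %*% matrix(a, nrow = d[axis])
  dim(a) <- da
  aperm(a, order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Separable 3D Gaussian blur of each volume, with the kernel width given
#' as full width at half maximum in mm (`sigma = fwhm / (2 sqrt(2 ln 2))`
#' per axis, converted to voxels by the axis voxel size).  Reflective
#' boundaries conserve total intensity.  A practical size for single-echo
#' EPI is 1.5-2x the minimum voxel dimension.
#'
#' @param vol A [volume4d()].
#' @param fwhm_mm Kernel FWHM in mm (0 = identity).
#' @return Blurred `volume4d`.
#' @export
gaussian_blur <- function(vol, fwhm_mm) {
  if (fwhm_mm < 0) stop2("fwhm must be non-negative")
  if (fwhm_mm == 0) return(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$grid$voxel_size
  Ws <- lapply(1:3, function(a) gauss_conv_matrix(vol$grid$dims[a], sigma[a]))
  out <- vol$data
  for (a in 1:3) out <- apply_axis(out, a, Ws[[a]])
  vol_with(vol, out)
}

# ---- connected components & morphology -----------------------------------

shift3 <- function(arr, axis, by, fill = Inf) {
  d <- dim(arr)
  out <- array(fill, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (by > 0) { idx_dst[[axis]] <- (1 + by):n; idx_src[[axis]] <- 1:(n - by) }
  else { idx_dst[[axis]] <- 1:(n + by); idx_src[[axis]] <- (1 - by):n }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# 6-connected component labelling by iterative minimum propagation.
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(Inf, d)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    new <- lab
    for (a in 1:3) for (s in c(-1, 1))
      new <- pmin(new, shift3(lab, a, s))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!mask] <- 0
  relab <- array(0L, d)
  u <- setdiff(unique(as.vector(lab)), 0)
  for (i in seq_along(u)) relab[lab == u[i]] <- i
  relab
}

fill_holes <- function(mask) {
  bg <- label_components(!mask)
  d <- dim(mask)
  border <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]))
  border <- setdiff(border, 0L)
  mask | (bg > 0 & !(bg %in% border))
}

erode6 <- function(mask) {
  out <- mask
  for (a in 1:3) for (s in c(-1, 1))
    out <- out & shift3(mask, a, s, fill = FALSE)
  out
}

#' Automatic EPI brain mask
#'
#' Thresholds the temporal mean image at an automatically chosen clip level
#' (Ridler-Calvard two-class iteration), keeps the largest 6-connected
#' component and fills interior holes.  When an anatomical mask is supplied
#' the EPI mask is intersected with it.  The mask is never multiplied into
#' the EPI data itself: it is returned for use in summary statistics so the
#' full field of view remains visible downstream.
#'
#' @param vol A [volume4d()].
#' @param anat_mask Optional logical 3D array on the same grid.
#' @return Logical 3D array.
#' @export
compute_epi_automask <- function(vol, anat_mask = NULL) {
  tmean <- array(rowMeans(matrix(vol$data, ncol = n_volumes(vol))),
                 dim = vol$grid$dims)
  if (max(tmean) <= 0) stop2("cannot automask an all-zero volume")
  thr <- mean(tmean)
  for (i in 1:100) {
    lo <- mean(tmean[tmean <= thr]); hi <- mean(tmean[tmean > thr])
    new <- (lo + hi) / 2
    if (!is.finite(new) || abs(new - thr) < 1e-9 * max(tmean)) break
    thr <- new
  }
  mask <- tmean > thr
  if (!any(mask)) stop2("automask threshold removed every voxel")
  lab <- label_components(mask)
  counts <- tabulate(lab[lab > 0])
  mask <- lab == which.max(counts)
  mask <- fill_holes(mask)
  if (!is.null(anat_mask)) mask <- mask & anat_mask
  if (!any(mask)) stop2("mask empty after anatomical intersection")
  mask
}

#' Scale each voxel's run time series to percent of its run mean
#'
#' `out = min(200, 100 * x / mean)` per voxel within each run; voxels with
#' non-positive mean are set to 0 across time.  After scaling, regression
#' effect estimates carry units of BOLD percent signal change.  Applied to
#' the full field of view; the mask argument is accepted for interface
#' symmetry with other stages but the scaling is deliberately not
#' restricted to it.
#'
#' @param vol A [volume4d()].
#' @param mask Unused (see above); retained so stage signatures match.
#' @return `volume4d` with `units = "percent"` and run means of 100.
#' @export
scale_percent <- function(vol, mask = NULL) {
  Y <- vol_as_tv(vol)
  for (ix in run_index(vol$runs)) {
    m <- colMeans(Y[ix, , drop = FALSE])
    pos <- m > 0
    Yr <- Y[ix, , drop = FALSE]
    Yr[, pos] <- pmin(200, 100 * sweep(Yr[, pos, drop = FALSE], 2, m[pos], "/"))
    Yr[, !pos] <- 0
    Y[ix, ] <- Yr
  }
  out <- tv_as_vol(Y, vol)
  out$units <- "percent"
  out
}

#' Clip temporal spikes
#'
#' A simple despike: per-voxel baseline-polynomial detrend, residuals
#' clipped to +/- 3 MADN, trend restored.  This truncates extreme
#' excursions while leaving ordinary fluctuations untouched (an
#' intentionally approximate stand-in for smoother squashing functions).
#'
#' @param vol A [volume4d()].
#' @return Despiked `volume4d`.
#' @export
despike_volume <- function(vol) {
  Y <- vol_as_tv(vol)
  R <- detrend_residuals(Y, vol$runs, vol$tr)
  lim <- 3 * 1.4826 * col_medians(abs(R))
  Rc <- pmin(pmax(R, rep(-lim, each = nrow(R))), rep(lim, each = nrow(R)))
  tv_as_vol(Y - R + Rc, vol)
}

#' Fit T2* decay and optimally combine echoes
#'
#' Per voxel, a log-linear least-squares fit of the temporal-mean signal
#' against echo time yields T2* (clamped to 2-300 ms) and S0; echoes are
#' then averaged with BOLD-contrast-optimal weights
#' `w_i = TE_i exp(-TE_i / T2*)`, normalized to sum to one.  Voxels with a
#' non-positive mean at any echo are marked invalid and receive uniform
#' weights.
#'
#' @param es An [echo_set()] with at least 2 echoes.
#' @param mask Optional logical 3D array restricting the fit (elsewhere
#'   weights are uniform).
#' @return List with `combined` ([volume4d()]) and `weights` (class
#'   `oc_weights`: arrays `t2star` (ms), `s0`, `valid`, and voxel x echo
#'   matrix `w`).
#' @export
fit_t2star_and_combine <- function(es, mask = NULL) {
  ne <- length(es$echoes)
  if (ne < 2L) stop2("optimal combination requires at least 2 echoes")
  te <- es$echo_times
  d <- es$echoes[[1]]$grid$dims
  nv <- prod(d)
  M <- sapply(es$echoes, function(e) rowMeans(matrix(e$data, nrow = nv)))
  valid <- rowSums(M <= 0) == 0
  if (!is.null(mask)) valid <- valid & as.vector(mask)
  L <- log(pmax(M, .Machine$double.eps))
  teC <- te - mean(te)
  slope <- (L %*% teC) / sum(teC^2)
  t2star <- ifelse(valid & slope < 0, clamp(-1 / slope, 2, 300), NA_real_)
  # intercept of the log-linear fit is log(S0)
  s0 <- exp(rowMeans(L) - slope * mean(te))
  w <- matrix(1 / ne, nv, ne)
  ok <- which(!is.na(t2star))
  if (length(ok)) {
    wv <- sapply(te, function(x) x * exp(-x / t2star[ok]))
    w[ok, ] <- wv / rowSums(wv)
  }
  nt <- n_volumes(es$echoes[[1]])
  comb <- matrix(0, nv, nt)
  for (i in seq_len(ne))
    comb <- comb + w[, i] * matrix(es$echoes[[i]]$data, nrow = nv)
  combined <- vol_with(es$echoes[[1]], array(comb, dim = c(d, nt)))
  weights <- structure(list(t2star = array(t2star, d), s0 = array(s0, d),
                            valid = array(valid, d), w = w,
                            echo_times = te),
                       class = "oc_weights")
  list(combined = combined, weights = weights)
}
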