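# Preprocessing blocks: tcat trimming, outlier counting, slice timing,
# registration, single-step resampling, blurring, masking, scaling and
# multi-echo combination.

test_that("initial-volume removal trims each run and validates n", {
  ph <- quiet_phantom()
  v <- ph$data
  expect_identical(remove_initial_volumes(v, 0), v)
  expect_identical(n_volumes(remove_initial_volumes(v, 4)),
                   n_volumes(v) - 4L)
  expect_error(remove_initial_volumes(v, n_volumes(v)), "cannot remove")
  # per-run: two runs of 10 each lose n volumes apiece
  v2 <- volume4d(v$data, grid = v$grid, tr = v$tr, runs = c(10, 10))
  expect_identical(remove_initial_volumes(v2, 2)$runs, c(8L, 8L))
})

test_that("temporal outlier fraction finds planted spikes at the right rate", {
  ph <- quiet_phantom()
  v <- ph$data
  mask <- ph$truth$brain_mask
  of0 <- temporal_outlier_fraction(v, mask)
  expect_true(all(of0 >= 0 & of0 <= 1))
  # constant data -> no outliers anywhere
  vc <- volume4d(array(5, c(6, 6, 4, 12)))
  expect_equal(max(temporal_outlier_fraction(vc, array(TRUE, c(6, 6, 4)))), 0)
  # +10 sigma spike in ~10% of mask voxels at volume 7
  set.seed(3)
  vox <- which(as.vector(mask))
  hit <- sample(vox, round(0.1 * length(vox)))
  sigma <- 0.005 * mean(v$data[, , , 1][mask])
  spiked <- v
  flat <- matrix(spiked$data, ncol = n_volumes(v))
  flat[hit, 7] <- flat[hit, 7] + 10 * sigma
  spiked$data <- array(flat, dim(v$data))
  of <- temporal_outlier_fraction(spiked, mask)
  expect_gt(of[7], 0.08)
  expect_lt(of[7], 0.12)
  expect_error(temporal_outlier_fraction(v, array(FALSE, dim(mask))), "mask")
})

test_that("pre-steady-state detection counts the brightened leading volumes", {
  ph <- static_phantom()
  v <- ph$data
  mask <- ph$truth$brain_mask
  expect_identical(detect_pre_steady_state(v, mask), 0L)
  v2 <- v
  v2$data[, , , 1] <- v$data[, , , 1] * 1.10
  v2$data[, , , 2] <- v$data[, , , 2] * 1.10
  expect_identical(detect_pre_steady_state(v2, mask), 2L)
})

test_that("slice-timing correction is exact on aligned/constant input and
           phase-accurate for sinc on a known sinusoid", {
  nt <- 80; tr <- 2; f <- 0.05
  st <- c(0, tr / 2, 0, tr / 2)
  dat <- array(0, c(6, 6, 4, nt))
  for (z in 1:4) for (t in 1:nt)
    dat[, , z, t] <- 100 + 10 * sin(2 * pi * f * ((t - 1) * tr + st[z]))
  v <- volume4d(dat, tr = tr, slice_times = st)
  # already aligned slices are untouched
  v0 <- volume4d(dat, tr = tr, slice_times = rep(0, 4))
  expect_lt(max(abs(slice_time_correct(v0, "cubic")$data - dat)), 1e-10)
  # constant series unchanged exactly
  vc <- volume4d(array(3, c(4, 4, 2, 10)), tr = 2, slice_times = c(0, 1))
  expect_equal(slice_time_correct(vc, "cubic")$data, vc$data)
  # sinc interpolation: phase error under 1 degree mid-series
  out <- slice_time_correct(v, "wsinc9", align_to = 0)
  mid <- 30:50
  ideal <- 100 + 10 * sin(2 * pi * f * ((mid - 1) * tr))
  phase_err_deg <- asin(min(1, max(abs(out$data[3, 3, 2, mid] - ideal)) / 10)) *
    180 / pi
  expect_lt(phase_err_deg, 1)
  expect_error(slice_time_correct(volume4d(dat, tr = tr)), "slice timing")
})

test_that("minimum-outlier reference selection uses the argmin with early ties", {
  ph <- quiet_phantom()
  v <- ph$data
  mask <- ph$truth$brain_mask
  # all-equal fractions tie to the first volume
  vc <- volume4d(array(rep(ph$data$data[, , , 1], 12), c(dim(mask), 12)))
  expect_identical(select_min_outlier_reference(vc, mask), 1L)
  # spiked volume is never chosen
  spiked <- v
  spiked$data[, , , 5][mask] <- spiked$data[, , , 5][mask] * 1.5
  expect_false(select_min_outlier_reference(spiked, mask) == 5L)
})

test_that("rigid motion estimation recovers injected transforms", {
  ph <- make_phantom(list(n_volumes = 6, motion_amp = 0, noise_pct = 0.2),
                     seed = 3)
  inj <- rbind(c(0, 0, 0, 0, 0, 0),
               c(0, 0, 0, 0, 2, 0),      # +2 mm x-translation
               c(3, 0, 0, 0, 0, 0),      # +3 degree roll
               c(0, 0, 0, 1, 0, 0),
               c(0, 2, 0, 0, -1.5, 0),
               c(1, -1, 0.5, 0.5, 1, -0.5))
  vm <- apply_rigid_motion(ph$data, inj, kernel = "cubic")
  mp <- estimate_rigid_motion(vm, 1)
  err <- abs(unclass(mp) - inj)
  expect_lt(abs(unclass(mp)[2, 5] - 2), 0.1)   # 2.0 +/- 0.1 mm
  expect_lt(abs(unclass(mp)[3, 1] - 3), 0.2)   # 3.0 +/- 0.2 degrees
  expect_lte(median(err[-1, 1:3]), 0.2)
  expect_lte(median(err[-1, 4:6]), 0.1)
  # duplicate volumes give (near) zero parameters
  dup <- volume4d(array(rep(ph$data$data[, , , 1], 3), c(32, 32, 20, 3)),
                  grid = ph$data$grid, tr = ph$data$tr)
  mp0 <- estimate_rigid_motion(dup, 1)
  expect_lt(max(abs(unclass(mp0))), 1e-3)
})

test_that("concatenated transforms compose and resample exactly once", {
  ph <- static_phantom()
  v <- ph$data
  # identity chain is the identity
  out <- apply_concatenated_transform(v)
  expect_equal(out$data, v$data)
  # two pure translations equal the single summed translation
  t1 <- diag(4); t1[1, 4] <- 2.5
  t2 <- diag(4); t2[2, 4] <- -1.5
  a <- apply_concatenated_transform(v, epi2anat = solve(t1),
                                    anat2final = solve(t2))
  t12 <- diag(4); t12[1, 4] <- 2.5; t12[2, 4] <- -1.5
  b <- apply_concatenated_transform(v, epi2anat = solve(t12))
  expect_lt(max(abs(a$data - b$data)), 1e-6)
  expect_error(apply_concatenated_transform(v, epi2anat = matrix(0, 4, 4)),
               "invertible")
})

test_that("one-step resampling smooths less than sequential two-step", {
  # delta image: the single interpolation preserves a higher peak
  d <- c(16, 16, 10)
  img <- array(0, d); img[8, 8, 5] <- 1
  v <- volume4d(img, grid = make_grid(d, c(3, 3, 4)))
  sh <- function(dx) { m <- diag(4); m[1, 4] <- dx; m }
  one <- apply_concatenated_transform(v, epi2anat = solve(sh(1.4)),
                                      anat2final = solve(sh(1.3)))
  s1 <- apply_concatenated_transform(v, epi2anat = solve(sh(1.4)))
  two <- apply_concatenated_transform(s1, epi2anat = solve(sh(1.3)))
  expect_gte(max(one$data), max(two$data))
})

test_that("gaussian blur conserves intensity and matches the analytic peak", {
  ph <- static_phantom()
  v <- ph$data
  expect_identical(gaussian_blur(v, 0), v)
  b <- gaussian_blur(v, 6)
  expect_lt(abs(sum(b$data) - sum(v$data)) / abs(sum(v$data)), 1e-6)
  # centred delta: peak matches the separable analytic Gaussian
  d <- c(21, 21, 21)
  img <- array(0, d); img[11, 11, 11] <- 1
  dv <- volume4d(img, grid = make_grid(d, c(3, 3, 3)))
  bb <- gaussian_blur(dv, 6)
  sg <- 6 / (2 * sqrt(2 * log(2))) / 3      # sigma in voxels
  kern <- exp(-(-10:10)^2 / (2 * sg^2)); kern <- kern / sum(kern)
  expect_lt(abs(max(bb$data) - max(kern)^3) / max(kern)^3, 0.02)
  expect_error(gaussian_blur(v, -1), "non-negative")
})

test_that("automask recovers the phantom brain and respects the anat mask", {
  ph <- static_phantom()
  m <- compute_epi_automask(ph$data)
  truth <- ph$truth$brain_mask
  dice <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_gte(dice, 0.95)
  sub <- truth & (ph$truth$tissue == 3L)   # strictly inside the EPI mask
  expect_identical(compute_epi_automask(ph$data, sub), sub)
  z <- volume4d(array(0, c(6, 6, 4, 5)))
  expect_error(compute_epi_automask(z), "all-zero")
})

test_that("percent scaling maps run means to 100 with the 200 cap", {
  v <- volume4d(array(c(1, 2, 3), c(1, 1, 1, 3)))
  expect_equal(as.vector(scale_percent(v)$data), c(50, 100, 150))
  v2 <- volume4d(array(c(1, 9), c(1, 1, 1, 2)))
  expect_equal(as.vector(scale_percent(v2)$data), c(20, 180))
  ph <- quiet_phantom()
  s <- scale_percent(ph$data)
  expect_identical(s$units, "percent")
  # in-brain voxels have fluctuations far below the cap: mean exactly 100
  Y <- t(matrix(s$data, ncol = n_volumes(s)))
  sel <- as.vector(ph$truth$brain_mask)
  expect_lt(max(abs(colMeans(Y[, sel]) - 100)), 1e-6)
  expect_true(all(Y[, sel] < 200))
  # idempotence on the cap-free region: means are already 100
  s2 <- scale_percent(s)
  Y2 <- t(matrix(s2$data, ncol = n_volumes(s2)))
  expect_lt(max(abs(Y2[, sel] - Y[, sel])), 1e-9)
})

test_that("T2* fitting and optimal combination match closed forms", {
  ph <- make_phantom(list(n_volumes = 8, n_echoes = 3, motion_amp = 0,
                          noise_pct = 0, drift_pct = 0), seed = 4)
  oc <- fit_t2star_and_combine(ph$data)
  ok <- ph$truth$brain_mask
  expect_lt(max(abs(oc$weights$t2star[ok] - ph$truth$t2star[ok]),
                na.rm = TRUE), 1e-6)
  # closed-form weights for TEs (10, 30) at T2* = 20 ms
  w <- c(10 * exp(-0.5), 30 * exp(-1.5))
  w <- w / sum(w)
  expect_equal(w, c(0.4754, 0.5246), tolerance = 1e-4)
  dims <- c(4, 4, 2)
  mk <- function(te) volume4d(array(1000 * exp(-te / 20), c(dims, 3)),
                              grid = make_grid(dims), tr = 2)
  es <- echo_set(list(mk(10), mk(30)), c(10, 30))
  oc2 <- fit_t2star_and_combine(es)
  expect_equal(unname(oc2$weights$w[1, ]), w, tolerance = 1e-6)
  # identical echoes combine to themselves (weights sum to 1)
  es3 <- echo_set(list(mk(10), mk(10 + 1e-9)), c(10, 20))
  expect_lt(max(abs(fit_t2star_and_combine(es3)$combined$data -
                    es3$echoes[[1]]$data)) /
            max(es3$echoes[[1]]$data), 1e-6)
})

test_that("optimally combined series beats the best single echo on CNR", {
  tim <- list(classes = list(on = list(list(
    onset = c(10, 40, 70), duration = rep(NA_real_, 3),
    modulators = matrix(0, 3, 0)))))
  class(tim) <- "timing_set"
  ph <- make_phantom(list(n_volumes = 50, n_echoes = 3, motion_amp = 0,
                          noise_pct = 1.5, slice_pattern = "none",
                          task = list(timing = tim, betas_pct = c(on = 2))),
                     seed = 11)
  er <- event_regressors(tim, "on", basis_spec("GAM"), "time", 50, 2.2)
  cnr <- function(v) {
    Y <- t(matrix(v$data, ncol = 50))
    sel <- as.vector(ph$truth$task$mask)
    b <- qr.coef(qr(cbind(1, er$X)), Y[, sel])[2, ]
    r <- Y[, sel] - cbind(1, er$X) %*% qr.coef(qr(cbind(1, er$X)), Y[, sel])
    mean(b / apply(r, 2, sd))
  }
  oc <- fit_t2star_and_combine(ph$data)
  expect_gte(cnr(oc$combined), max(sapply(ph$data$echoes, cnr)))
})
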