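# Regression model: HRF bases, event/nuisance/bandpass regressors,
# censoring, design assembly, GLM fitting, contrasts and DF accounting.

test_that("HRF bases honour their normalization conventions", {
  # a 1 s duration-modulated block peaks at exactly 1
  s <- sample_basis(basis_spec("dmUBLOCK", duration = 1), dt = 0.01)
  expect_equal(max(s$values), 1, tolerance = 1e-6)
  # GAM peaks at exactly 1 at t = p*q
  g <- basis_spec("GAM")
  expect_equal(gam_t <- 8.6 * 0.547, 4.7042)
  expect_equal(sample_basis(g, dt = 1e-3)$values[round(gam_t / 1e-3) + 1],
               1, tolerance = 1e-6)
  # TENT bases form a partition of unity inside the window
  te <- sample_basis(basis_spec("TENT", b = 0, c = 12, n = 7), dt = 0.05,
                     length = 12)
  inside <- te$time > 0 & te$time < 12
  expect_lt(max(abs(rowSums(te$values)[inside] - 1)), 1e-9)
  # longer blocks have larger (non-decreasing) peaks
  pk <- sapply(c(1, 2, 5, 10, 20), function(d)
    max(sample_basis(basis_spec("BLOCK", duration = d), dt = 0.02,
                     length = 60)$values))
  expect_true(all(diff(pk) >= -1e-9))
  expect_gt(pk[5], pk[2])
  expect_error(basis_spec("WAV"), "unsupported")
})

test_that("event regressors implement time/AM1/AM2/IM and duration modulation", {
  ts <- timing_set(list(ev = list(list(
    onset = c(0, 20, 40, 60, 80),
    duration = rep(NA_real_, 5),
    modulators = matrix(c(1, 2, 3, 4, 5), ncol = 1)))))
  # IM: one column per event
  im <- event_regressors(ts, "ev", basis_spec("GAM"), "IM", 60, 2)
  expect_identical(ncol(im$X), 5L)
  # AM2 with equal modulators has an identically zero modulated column
  ts0 <- timing_set(list(ev = list(list(
    onset = c(0, 20, 40), duration = rep(NA_real_, 3),
    modulators = matrix(2, 3, 1)))))
  expect_warning(am2 <- event_regressors(ts0, "ev", basis_spec("GAM"),
                                         "AM2", 40, 2), "zero variance")
  expect_identical(max(abs(am2$X[, 2])), 0)
  # AM1 scales the response by the modulator
  am1 <- event_regressors(ts0, "ev", basis_spec("GAM"), "AM1", 40, 2)
  tm <- event_regressors(ts0, "ev", basis_spec("GAM"), "time", 40, 2)
  expect_equal(am1$X[, 1], 2 * tm$X[, 1], tolerance = 1e-9)
  # single event at t=0, dmUBLOCK dur 1, TR 2: column peak ~ 1
  ts1 <- timing_set(list(e = list(list(onset = 0, duration = 1,
                                       modulators = matrix(0, 1, 0)))))
  er <- event_regressors(ts1, "e", basis_spec("dmUBLOCK"), "time", 30, 2)
  ref <- max(epiproc:::block_response(seq(0, 58, 2), 1))
  expect_equal(max(er$X), ref, tolerance = 1e-9)
  expect_lt(abs(max(er$X) - 1), 0.2)   # volume grid may straddle the peak
  # events after the run end are dropped with a warning
  ts2 <- timing_set(list(e = list(list(onset = c(5, 500),
                                       duration = rep(NA_real_, 2),
                                       modulators = matrix(0, 2, 0)))))
  expect_warning(event_regressors(ts2, "e", basis_spec("GAM"), "time",
                                  30, 2), "dropped")
})

test_that("bandpass regressors enumerate DFT frequencies and predict DF loss", {
  # the standard low-frequency band at TR = 2 costs 60% of the DFs; at
  # TR = 1 it costs 80%
  expect_equal(bandpass_regressors(100, 2, 0, 0.1)$dfloss_predicted, 0.60)
  expect_equal(bandpass_regressors(100, 1, 0, 0.1)$dfloss_predicted, 0.80)
  # N=200, TR=2, keep [0.01, 0.1]: 125 nuisance columns by enumeration
  bp <- bandpass_regressors(200, 2, 0.01, 0.1)
  expect_identical(ncol(bp$X), 125L)
  # empirical fraction close to the analytic prediction for several N
  for (N in c(100, 200, 500)) {
    bpN <- bandpass_regressors(N, 2, 0.01, 0.1)
    expect_lt(abs(ncol(bpN$X) / N - bpN$dfloss_predicted), 0.05)
  }
  expect_error(bandpass_regressors(100, 2, 0.2, 0.1), "band")
  expect_error(bandpass_regressors(100, 2, 0, 0.5), "Nyquist")
})

test_that("bandpass-in-model equals FFT band rejection on an uncensored run", {
  N <- 96; tr <- 2
  set.seed(5)
  y <- rnorm(N)
  bp <- bandpass_regressors(N, tr, 0.01, 0.1)
  X <- cbind(1, bp$X)
  resid <- y - X %*% qr.coef(qr(X), y)
  # FFT route: zero every coefficient outside the keep band (and DC)
  f <- fft(y)
  freqs <- (0:(N - 1)) / (N * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)   # fold to [0, Nyquist]
  keep <- freqs >= 0.01 - 1e-9 & freqs <= 0.1 + 1e-9
  f[!keep] <- 0
  fft_resid <- Re(fft(f, inverse = TRUE)) / N
  expect_lt(rms(resid - fft_resid), 1e-8)
})

test_that("motion regressors produce the demean/deriv/per-run column sets", {
  set.seed(6)
  P <- matrix(rnorm(40 * 6, sd = 0.2), 40, 6)
  P[1, ] <- 0
  mp <- motion_params(P, 1)
  m1 <- motion_regressors(mp, c("demean", "deriv"), run_lengths = 40)
  expect_identical(ncol(m1$X), 12L)
  expect_lt(max(abs(colMeans(m1$X[, 1:6]))), 1e-12)
  m2 <- motion_regressors(mp, c("demean", "deriv"), per_run = TRUE,
                          run_lengths = c(20, 20))
  expect_identical(ncol(m2$X), 24L)
  expect_identical(max(abs(m2$X[21:40, 1:12])), 0)   # block-diagonal
  mp0 <- motion_params(matrix(0, 10, 6), 1)
  expect_identical(max(abs(motion_regressors(mp0, run_lengths = 10)$X)), 0)
  expect_error(motion_regressors(mp, "quadratic"), "unknown")
})

test_that("baseline polynomials follow the auto rule and are orthogonal", {
  b0 <- baseline_regressors(20, 2, 0)
  expect_identical(ncol(b0$X), 1L)
  # 300 s run: polort = 1 + floor(300/150) = 3, so 4 columns
  ba <- baseline_regressors(150, 2, "auto")
  expect_identical(ba$polort, 3L)
  expect_identical(ncol(ba$X), 4L)
  G <- crossprod(ba$X)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-10)
  # per-run: block diagonal with one constant per run
  b2 <- baseline_regressors(c(30, 30), 2, 1)
  expect_identical(ncol(b2$X), 4L)
  expect_identical(max(abs(b2$X[31:60, 1:2])), 0)
})

test_that("ROI principal components recover a planted source", {
  ph <- static_phantom()
  v <- ph$data
  roi <- roi_volume(v$grid, ph$truth$tissue == 3L,
                    c(core = 1L))
  set.seed(8)
  src <- rnorm(n_volumes(v))
  sel <- epiproc:::erode6(ph$truth$tissue == 3L)
  flat <- matrix(v$data, ncol = n_volumes(v))
  flat[as.vector(sel), ] <- flat[as.vector(sel), ] +
    outer(runif(sum(sel), 1, 3), src)
  v$data <- array(flat, dim(v$data))
  pc <- roi_pc_regressors(v, roi, "core", k = 1)
  expect_gt(abs(cor(pc$X[, 1], src)), 0.99)
  expect_equal(crossprod(pc$X)[1, 1], 1, tolerance = 1e-9)
  # a 1-voxel ROI vanishes under erosion
  tiny <- array(0L, v$grid$dims); tiny[2, 2, 2] <- 1L
  roi2 <- roi_volume(v$grid, tiny, c(dot = 1L))
  expect_error(roi_pc_regressors(v, roi2, "dot", 1), "erosion")
})

test_that("Enorm is the L2 norm of parameter differences, zero at run starts", {
  P <- matrix(0, 6, 6)
  expect_identical(enorm_series(P), rep(0, 6))
  P[4, 1] <- 0.3
  e <- enorm_series(P)
  expect_equal(e[4], 0.3)
  expect_equal(e[5], 0.3)        # stepping back down also moves
  P2 <- matrix(0, 4, 6); P2[2, 1:3] <- c(0.1, 0.2, 0.2)
  expect_equal(enorm_series(P2)[2], 0.3)
  # no difference across run breaks
  P3 <- matrix(0, 4, 6); P3[3, 1] <- 5
  expect_identical(enorm_series(P3, c(2, 2))[3], 0)
})

test_that("censoring applies the both-time-points motion rule and the
           outlier rule", {
  e <- c(0, 0, 0, 0.35, 0, 0)
  cs <- build_censor(e, rep(0, 6), 0.3, 0.05)
  expect_identical(which(!cs$keep), c(3L, 4L))
  cs2 <- build_censor(rep(0, 3), c(0.01, 0.06, 0.02), 0.3, 0.05)
  expect_identical(which(!cs2$keep), 2L)
  cs3 <- build_censor(rep(0.1, 5), rep(0.01, 5), 0.3, 0.05)
  expect_true(all(cs3$keep))
  # disabled criteria
  expect_true(all(build_censor(e, rep(0, 6), NA, NA)$keep))
})

test_that("design assembly counts columns, deletes censored rows, rejects
           duplicates", {
  N <- 220
  set.seed(10)
  base <- baseline_regressors(N, 2.2, 1)
  mot <- list(X = matrix(rnorm(N * 12), N), labels = sprintf("m%02d", 1:12))
  cs <- build_censor(c(rep(0, 100), 0.4, rep(0, N - 101)), rep(0, N))
  X <- assemble_design(list(baseline = base, motion = mot), cs, N, 2.2)
  expect_identical(ncol(X$X), ncol(base$X) + 12L)
  expect_identical(sum(!X$censor$keep), 2L)
  v <- volume4d(array(rnorm(8 * N), c(2, 2, 2, N)), tr = 2.2)
  g <- fit_glm(v, X)
  expect_equal(g$df, (N - 2L) - ncol(X$X))
  bad <- list(X = matrix(0, N, 1), labels = "m01")
  expect_error(assemble_design(list(baseline = base, motion = mot,
                                    extra = bad), cs, N, 2.2), "duplicate")
})

test_that("GLM recovers noiseless coefficients with orthogonal residuals
           and AR(1) prewhitening is unbiased for white noise", {
  N <- 60
  set.seed(12)
  X0 <- cbind(rnorm(N), rnorm(N))
  parts <- list(baseline = baseline_regressors(N, 2, 0),
                "stim:a" = list(X = X0[, 1, drop = FALSE], labels = "a"),
                "stim:b" = list(X = X0[, 2, drop = FALSE], labels = "b"))
  D <- assemble_design(parts, NULL, N, 2)
  beta <- c(3, 1.5, -2)
  y <- cbind(D$X) %*% beta
  v <- volume4d(array(rep(y, each = 4), c(2, 2, 1, N)), tr = 2)
  g <- fit_glm(v, D)
  expect_lt(max(abs(g$betas[1, ] - beta)), 1e-8)
  r <- vol_as_tv(g$errts)
  expect_lt(max(abs(crossprod(D$X, r))), 1e-6 * sqrt(sum(y^2)))
  # white noise: AR(1) betas agree with OLS betas
  vn <- volume4d(array(rep(y, each = 4) + rnorm(4 * N, sd = 0.5),
                       c(2, 2, 1, N)), tr = 2)
  g0 <- fit_glm(vn, D, whiten = "none")
  g1 <- fit_glm(vn, D, whiten = "ar1")
  expect_lt(abs(g1$rho), 0.25)
  expect_lt(max(abs(g0$betas - g1$betas)), 0.05)
  # rank deficiency is reported with the offending columns
  parts$`stim:c` <- list(X = X0[, 1, drop = FALSE] * 2, labels = "cdup")
  D2 <- assemble_design(parts, NULL, N, 2)
  expect_error(fit_glm(v, D2), "rank deficient.*cdup")
})

test_that("censored-row deletion equals fitting with model-predicted rows", {
  # projection identity: deleting rows is the same as replacing those
  # rows' data with the model's own prediction
  N <- 30
  set.seed(13)
  X <- cbind(1, rnorm(N), rnorm(N))
  y <- X %*% c(1, 2, -1) + rnorm(N)
  drop_ix <- c(7, 19)
  keep <- setdiff(seq_len(N), drop_ix)
  b_del <- qr.coef(qr(X[keep, ]), y[keep])
  y2 <- y; y2[drop_ix] <- X[drop_ix, ] %*% b_del
  b_rep <- qr.coef(qr(X), y2)
  expect_lt(max(abs(b_del - b_rep)), 1e-10)
})

test_that("general linear tests evaluate contrasts and reject bad weights", {
  N <- 50
  set.seed(14)
  parts <- list(baseline = baseline_regressors(N, 2, 0),
                "stim:task" = list(X = cbind(rnorm(N)), labels = "task"),
                "stim:ctrl" = list(X = cbind(rnorm(N)), labels = "ctrl"))
  D <- assemble_design(parts, NULL, N, 2)
  y <- D$X %*% c(0, 3, 1) + rnorm(N, sd = 0.1)
  v <- volume4d(array(rep(y, each = 2), c(2, 1, 1, N)), tr = 2)
  g <- fit_glm(v, D)
  tc <- linear_test(g, c(task = 1, ctrl = -1), "T-C")
  expect_equal(unname(tc$estimate[1]), 2, tolerance = 0.15)
  mean_tc <- linear_test(g, c(task = 0.5, ctrl = 0.5), "meanTC")
  expect_equal(unname(mean_tc$estimate[1]), 2, tolerance = 0.15)
  ft <- linear_test(g, rbind(c(task = 1, ctrl = 0), c(task = 0, ctrl = 1)))
  expect_identical(ft$stat_type, "F")
  expect_true(all(ft$stat >= 0))
  expect_error(linear_test(g, c(nope = 1)), "unknown")
  expect_error(linear_test(g, c(task = 0, ctrl = 0)), "zero")
})

test_that("the DF ledger accounts exactly and flags overuse", {
  N <- 220
  set.seed(15)
  parts <- list(baseline = list(X = matrix(rnorm(N * 4), N),
                                labels = paste0("b", 1:4)),
                motion = list(X = matrix(rnorm(N * 12), N),
                              labels = paste0("m", 1:12)),
                physio = list(X = matrix(rnorm(N * 13), N),
                              labels = paste0("p", 1:13)))
  cs <- build_censor(c(rep(0, 50), 0.4, rep(0, N - 51)), rep(0, N))
  X <- assemble_design(parts, cs, N, 2.2)
  led <- compute_df_ledger(X)
  expect_identical(led$n_censored, 2L)
  expect_identical(led$df_remaining, 220L - 2L - 4L - 12L - 13L)
  expect_identical(led$df_remaining, 189L)
  expect_identical(led$n_total,
                   led$n_censored + sum(led$used) + led$df_remaining)
  expect_identical(led$flag, "none")
  # adding the standard bandpass at TR=2 consumes ~60% of the DFs
  bp <- bandpass_regressors(N, 2, 0, 0.1)
  X2 <- assemble_design(c(parts, list(bandpass = bp)), cs, N, 2)
  led2 <- compute_df_ledger(X2)
  expect_gt(led2$used[["bandpass"]] / N, 0.55)
  expect_identical(led2$flag, "warn")
})

test_that("design warnings flag collinearity, heavy censoring and
           censor-stimulus overlap", {
  N <- 80
  set.seed(16)
  s1 <- cbind(rnorm(N))
  parts <- list(baseline = baseline_regressors(N, 2, 0),
                "stim:a" = list(X = s1, labels = "a"),
                "stim:b" = list(X = s1 + rnorm(N, sd = 1e-4), labels = "b"))
  X <- assemble_design(parts, NULL, N, 2)
  w <- design_warnings(X)
  expect_true("stim_collinearity" %in% w$check)
  expect_identical(w$level[w$check == "stim_collinearity"], "severe")
  # clean design: empty warning list
  parts$`stim:b` <- list(X = cbind(rnorm(N)), labels = "b")
  Xc <- assemble_design(parts, NULL, N, 2)
  expect_identical(nrow(design_warnings(Xc)), 0L)
  # censoring concentrated inside one class's response windows
  ts <- timing_set(list(hit = list(list(onset = c(20, 60, 100),
                                        duration = rep(NA_real_, 3),
                                        modulators = matrix(0, 3, 0))),
                        miss = list(list(onset = c(140),
                                         duration = NA_real_,
                                         modulators = matrix(0, 1, 0)))))
  en <- rep(0, N); en[c(11, 32, 52)] <- 1   # volumes at 20/62/102 s
  cs <- build_censor(en, rep(0, N), 0.3, NA)
  Xo <- assemble_design(parts, cs, N, 2)
  wo <- design_warnings(Xo, ts)
  hit_rows <- wo[wo$check == "stim_censor_overlap", ]
  expect_true(any(grepl("'hit'", hit_rows$message)))
  expect_false(any(grepl("'miss'", hit_rows$message)))
})
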