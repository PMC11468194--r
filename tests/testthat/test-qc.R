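# Quality-control battery: TSNR, radial correlation, GCOR, correlation
# maps, alignment cost, flip check, ROI tables, variance lines, review
# aggregation and the HTML report.

test_that("TSNR is mean(baseline)/sd(residual) with the zero convention", {
  set.seed(31)
  n <- 40
  dat <- array(100, c(3, 3, 2, n))
  dat[1, 1, 1, ] <- 100 + rnorm(n, sd = 10)
  dat[2, 1, 1, ] <- 50          # constant voxel
  v <- volume4d(dat, tr = 2)
  ts <- tsnr_map(v)
  expect_identical(ts$units, "tsnr")
  expect_equal(ts$data[1, 1, 1, 1], 100 / sd(dat[1, 1, 1, ] -
                                             mean(dat[1, 1, 1, ])),
               tolerance = 0.05)
  expect_identical(ts$data[2, 1, 1, 1], 0)
  # TSNR ordering matches 1/sigma ordering for equal means
  sig <- c(2, 5, 10, 20)
  dat2 <- array(0, c(4, 1, 1, n))
  for (i in 1:4) dat2[i, 1, 1, ] <- 100 + rnorm(n, sd = sig[i])
  t2 <- tsnr_map(volume4d(dat2, tr = 2))
  expect_identical(order(t2$data[, 1, 1, 1], decreasing = TRUE), 1:4)
  expect_error(tsnr_map(volume4d(array(1, c(2, 2, 1, 5)))), "10 volumes")
})

test_that("radial correlation is 1 for identical series, low for noise,
           high in a coherent slab", {
  ph <- quiet_phantom()
  g <- ph$data$grid
  n <- 20
  # identical series everywhere
  share <- rnorm(n, sd = 2)
  same <- volume4d(array(rep(share, each = prod(g$dims)) + 100,
                         c(g$dims, n)), grid = g, tr = 2)
  rc1 <- radial_correlation(same)
  expect_lt(max(abs(rc1$data - 1)), 1e-6)
  # independent noise: median |r| small
  set.seed(32)
  noise <- volume4d(array(rnorm(prod(g$dims) * n), c(g$dims, n)),
                    grid = g, tr = 2)
  rcn <- radial_correlation(noise)
  expect_lt(median(abs(rcn$data)), 0.2)
  expect_true(all(abs(rcn$data) <= 1 + 1e-12))
  # coherent slab stands out against its surround
  slab <- noise
  sel <- array(FALSE, g$dims); sel[10:20, 10:20, 8:12] <- TRUE
  flat <- matrix(slab$data, ncol = n)
  flat[as.vector(sel), ] <- flat[as.vector(sel), ] +
    3 * rep(share, each = sum(sel))
  slab$data <- array(flat, dim(slab$data))
  rcs <- radial_correlation(slab)
  expect_gt(mean(rcs$data[, , , 1][sel]), mean(rcs$data[, , , 1][!sel]))
})

test_that("GCOR matches the brute-force pairwise correlation mean", {
  set.seed(33)
  n <- 30; nv <- 50
  Y <- matrix(rnorm(n * nv), n, nv)
  v <- volume4d(array(t(Y), c(5, 5, 2, n)))
  mask <- array(TRUE, c(5, 5, 2))
  expect_equal(gcor(v, mask), mean(cor(Y)), tolerance = 1e-12)
  # identical series: 1; two balanced anti-correlated groups: ~0
  one <- volume4d(array(rep(rnorm(n), each = 4), c(2, 2, 1, n)))
  expect_equal(gcor(one, array(TRUE, c(2, 2, 1))), 1, tolerance = 1e-12)
  s <- rnorm(n)
  anti <- array(0, c(2, 1, 2, n))
  anti[1, 1, 1, ] <- s; anti[2, 1, 1, ] <- s
  anti[1, 1, 2, ] <- -s; anti[2, 1, 2, ] <- -s
  expect_lt(gcor(volume4d(anti), array(TRUE, c(2, 1, 2))), 1e-12)
  # bounded on random phantoms
  for (seed in 1:3) {
    set.seed(seed)
    vr <- volume4d(array(rnorm(8 * 20), c(2, 2, 2, 20)))
    gv <- gcor(vr, array(TRUE, c(2, 2, 2)))
    expect_gte(gv, 0); expect_lte(gv, 1)
  }
  expect_error(gcor(v, array(FALSE, c(5, 5, 2))), "2 in-mask")
})

test_that("ROI-average correlation maps behave like corr_brain", {
  ph <- quiet_phantom()
  mask <- ph$truth$brain_mask
  cb <- average_roi_correlation_map(ph$data, mask)
  expect_true(all(abs(cb$data) <= 1 + 1e-12))
  # a voxel proportional to the regional mean correlates at 1
  v <- ph$data
  Y <- vol_as_tv(v)
  ref <- rowMeans(Y[, as.vector(mask)])
  flat <- matrix(v$data, ncol = n_volumes(v))
  flat[1, ] <- 5 * ref + 2
  flat[2, ] <- -ref
  v$data <- array(flat, dim(v$data))
  cb2 <- average_roi_correlation_map(v, mask)
  expect_gt(cb2$data[1, 1, 1, 1], 0.999)
  expect_lt(cb2$data[2, 1, 1, 1], 0)   # anti-correlated voxel is negative
  expect_error(average_roi_correlation_map(v, array(FALSE, dim(mask))),
               "empty")
})

test_that("seed correlation maps are censored-aware and default to two
           lateral seeds without a template", {
  ph <- quiet_phantom()
  v <- ph$data
  seeds <- default_seed_locations(v$grid)
  expect_length(seeds, 2)
  expect_length(default_seed_locations(v$grid, "template"), 3)
  sm <- seed_correlation_map(v, seeds[[1]])
  ijk <- round(grid_world_to_voxel(v$grid, seeds[[1]])) + 1
  expect_equal(sm$data[ijk[1], ijk[2], ijk[3], 1], 1, tolerance = 1e-9)
  # censoring excludes a spike volume from the correlation
  sp <- v
  sp$data[, , , 7] <- sp$data[, , , 7] * 3
  cs <- censor_series(keep = seq_len(n_volumes(v)) != 7)
  m_cens <- seed_correlation_map(sp, seeds[[1]], cs)
  m_ref <- seed_correlation_map(v, seeds[[1]], cs)
  expect_lt(max(abs(m_cens$data - m_ref$data)), 1e-9)
  expect_error(seed_correlation_map(v, c(1000, 0, 0)), "outside")
})

test_that("the local Pearson cost signs identity and contrast reversal", {
  img <- static_image()
  expect_equal(lpc_cost(img$img, img$img, img$grid), -1, tolerance = 1e-9)
  expect_equal(lpc_cost(img$img, -img$img, img$grid), 1, tolerance = 1e-9)
  set.seed(34)
  a <- array(rnorm(prod(img$grid$dims)), img$grid$dims)
  b <- array(rnorm(prod(img$grid$dims)), img$grid$dims)
  expect_lt(abs(lpc_cost(a, b, img$grid)), 0.1)
  expect_error(lpc_cost(array(1, c(4, 4, 4)), array(2, c(4, 4, 4)),
                        make_grid(c(4, 4, 4))), "variance")
})

test_that("the flip check identifies mirrored anatomy and ties on symmetry", {
  ph <- static_phantom()
  epi <- ph$data$data[, , , 1]
  anat <- ph$truth$s0
  fc <- left_right_flip_check(epi, anat, ph$data$grid)
  expect_identical(fc$verdict, "no_flip")
  fc2 <- left_right_flip_check(epi, epiproc:::mirror_x(anat), ph$data$grid)
  expect_identical(fc2$verdict, "flip_suspected")
  # perfectly symmetric image: inconclusive by construction
  sym <- anat + epiproc:::mirror_x(anat)
  fc3 <- left_right_flip_check(sym + 0 * epi, sym, ph$data$grid)
  expect_identical(fc3$verdict, "inconclusive")
})

test_that("ROI statistics report counts, depth and TSNR quantiles", {
  g <- make_grid(c(10, 10, 10))
  lab <- array(0L, c(10, 10, 10))
  lab[4:6, 4:6, 4:6] <- 1L            # 3x3x3 cube
  roi <- roi_volume(g, lab, c(cube = 1L))
  tv <- volume4d(array(100, c(10, 10, 10)), grid = g)
  tab <- roi_stats_table(tv, roi)
  expect_identical(tab$Nvox, 27L)
  expect_identical(tab$Dvox, 2L)
  expect_true(all(unlist(tab[, c("Tmin", "T25", "Tmed", "T75", "Tmax")]) == 100))
  # half the ROI zeroed: Nzer counted and shape warning set
  half <- tv
  half$data[4:6, 4:6, 4, 1] <- 0
  tab2 <- roi_stats_table(half, roi)
  expect_identical(tab2$Nzer, 9L)
  expect_match(tab2$warns, "shape")
  expect_error(roi_stats_table(tv, roi, "nope"), "unknown")
})

test_that("variance line detection flags the noisy column scale-free", {
  ph <- static_phantom()
  mask <- ph$truth$brain_mask
  set.seed(35)
  # homogeneous-noise series long enough for stable variance estimates
  v <- volume4d(array(100, c(ph$data$grid$dims, 40)) +
                  array(rnorm(prod(ph$data$grid$dims) * 40),
                        c(ph$data$grid$dims, 40)),
                grid = ph$data$grid, tr = ph$data$tr)
  expect_identical(nrow(variance_line_check(v, mask)), 0L)
  bad <- v
  bad$data[16, 16, , ] <- bad$data[16, 16, , ] +
    10 * array(rnorm(prod(dim(bad$data)[3:4])), dim(bad$data)[3:4])
  fl <- variance_line_check(bad, mask)
  expect_true(any(fl$x == 15 & fl$y == 15))
  # invariance to global intensity scaling
  sc <- bad
  sc$data <- sc$data * 7
  expect_identical(variance_line_check(sc, mask), fl)
})

test_that("review tables aggregate uvars files and flag outliers", {
  dir <- withr::local_tempdir()
  paths <- file.path(dir, sprintf("s%d.json", 1:3))
  write_uvars(list(subject_id = "s1", censor_frac = 0.02, tsnr_mean = 80), paths[1])
  write_uvars(list(subject_id = "s2", censor_frac = 0.15, tsnr_mean = 70), paths[2])
  write_uvars(list(subject_id = "s3", tsnr_mean = 90), paths[3])
  rt <- review_table(paths, criteria = "censor_frac ge 0.1")
  expect_identical(nrow(rt$table), 3L)
  expect_identical(rt$table$censor_frac[3], "")   # missing key -> blank
  expect_identical(basename(rt$outliers$file), "s2.json")
  # unparseable file listed, not fatal
  bad <- file.path(dir, "bad.json")
  writeLines("{not json", bad)
  rt2 <- review_table(c(paths, bad))
  expect_identical(rt2$failed, bad)
  expect_identical(nrow(rt2$table), 3L)
})

test_that("the HTML report has all section anchors, absent placeholders,
           verbatim warnings and censor shading", {
  ph <- quiet_phantom()
  dir <- withr::local_tempdir()
  cs <- build_censor(c(rep(0, 8), 0.5, rep(0, 5), 0.4, rep(0, 5)),
                     rep(0, 20), 0.3, 0.05)
  warns <- data.frame(check = "stim_collinearity", level = "severe",
                      message = "max |r| between stimulus regressors = 0.910")
  qc <- list(epi_ref = ph$data$data[, , , 1],
             censor = cs, warnings = warns,
             scalars = list(subject_id = "ph", tr = 2.2, gcor = 0.03))
  out <- render_apqc_html(qc, dir)
  html <- paste(readLines(out), collapse = "\n")
  for (id in c("vorig", "ve2a", "mot", "regr", "warns", "radcor", "qsumm"))
    expect_match(html, sprintf("id='%s'", id))
  expect_match(html, "absent")                      # missing maps
  expect_match(html, "max \\|r\\| between stimulus regressors = 0.910")
  expect_true(file.exists(file.path(dir, "mot.png")))
  # two censored intervals in the constructed censor series
  iv <- epiproc:::censored_intervals(cs$keep)
  expect_identical(nrow(iv), 2L)
})
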