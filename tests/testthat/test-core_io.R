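# Readers/writers: NIFTI round trips, column files, stimulus timing
# grammar, events tables and the uvars dictionary.

test_that("NIFTI round trip preserves data, affine, TR, slice times and units", {
  grid <- make_grid(c(8, 7, 6), c(3, 3, 4))
  set.seed(1)
  v <- volume4d(array(rnorm(8 * 7 * 6 * 5), c(8, 7, 6, 5)), grid = grid,
                tr = 2.2, slice_times = (0:5) / 6 * 2.2, units = "percent")
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(v, p)
  r <- read_nifti(p)
  expect_lt(max(abs(r$data - v$data)), 1e-6 * max(abs(v$data)))
  expect_lt(max(abs(r$grid$affine - grid$affine)), 1e-5)
  expect_equal(r$tr, 2.2, tolerance = 1e-6)  # TR is stored as float32
  expect_equal(r$slice_times, v$slice_times, tolerance = 1e-6)
  expect_identical(r$units, "percent")
})

test_that("3D anatomical files load as single-volume series without timing", {
  img <- static_image()
  v <- volume4d(img$img, grid = img$grid, tr = 1)
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(v, p)
  r <- read_nifti(p)
  expect_identical(n_volumes(r), 1L)
  expect_length(r$slice_times, 0)
})

test_that("zero header TR on 4D data falls back to 1 s with a warning", {
  p <- withr::local_tempfile(fileext = ".nii")
  img <- RNifti::asNifti(array(rnorm(4 * 4 * 3 * 6), c(4, 4, 3, 6)),
                         datatype = "double")
  RNifti::writeNifti(img, p)
  # zero out pixdim[4] (TR) directly in the header: the writer library
  # itself refuses to emit a zero time step
  con <- file(p, "r+b"); seek(con, 92, rw = "write")
  writeBin(0, con, size = 4); close(con)
  expect_warning(r <- read_nifti(p), "TR")
  expect_identical(r$tr, 1.0)
  expect_error(read_nifti(file.path(tempdir(), "nope.nii")), "exist")
})

test_that("column files parse comments and reject ragged or non-numeric rows", {
  p <- withr::local_tempfile()
  writeLines(c("# a comment", "0 0", "1 2", "3 4"), p)
  expect_equal(read_column_file(p), rbind(c(0, 0), c(1, 2), c(3, 4)))
  writeLines(c("0 0", "1 2 3"), p)
  expect_error(read_column_file(p), "line 2")
  writeLines(c("0 x"), p)
  expect_error(read_column_file(p), "non-numeric")
  m <- matrix(rnorm(12), 4, 3)
  write_column_file(m, p, comment = "test")
  expect_equal(read_column_file(p), m, tolerance = 1e-9)
})

test_that("stimulus timing grammar handles plain, married and empty rows", {
  p <- withr::local_tempfile()
  writeLines(c("10 40 90", "*", "10:4 40:2.5", "-1",
               "5*1.5 20*2.5:3"), p)
  ts <- read_stim_timing(p, "A")
  cl <- ts$classes$A
  expect_length(cl, 5)
  expect_equal(cl[[1]]$onset, c(10, 40, 90))
  expect_true(all(is.na(cl[[1]]$duration)))
  expect_length(cl[[2]]$onset, 0)
  expect_equal(cl[[3]]$duration, c(4, 2.5))
  expect_length(cl[[4]]$onset, 0)
  expect_equal(cl[[5]]$modulators[, 1], c(1.5, 2.5))
  expect_equal(cl[[5]]$duration, c(NA, 3))
})

test_that("malformed and negative timing tokens fail with file/row context", {
  p <- withr::local_tempfile()
  writeLines("10 oops 20", p)
  expect_error(read_stim_timing(p, "A"), "row 1.*oops")
  writeLines("-5 10", p)
  expect_error(read_stim_timing(p, "A"), "negative onset")
  writeLines(c("1*2 3"), p)
  expect_error(read_stim_timing(p, "A"), "mixed modulator")
})

test_that("timing write/read round trip is the identity on token sets", {
  tim <- make_task_timing(3, 120, c(go = 5, stop = 4), min_gap_s = 4,
                          durations = list(go = c(1, 3)),
                          modulators = TRUE, seed = 7)
  dir <- withr::local_tempdir()
  paths <- write_stim_timing(tim$timing, dir)
  back <- read_stim_timing(paths, names(paths))
  for (lab in names(tim$timing$classes)) {
    for (r in 1:3) {
      a <- tim$timing$classes[[lab]][[r]]
      b <- back$classes[[lab]][[r]]
      expect_equal(b$onset, a$onset, tolerance = 1e-8)
      expect_equal(b$duration, a$duration, tolerance = 1e-8)
      expect_equal(unname(b$modulators), unname(a$modulators),
                   tolerance = 1e-8)
    }
  }
})

test_that("events TSV and AFNI-style timing produce identical timing sets", {
  tim <- make_task_timing(2, 100, c(task = 4, control = 3), min_gap_s = 4,
                          seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_stim_timing(tim$timing, dir)
  tsv <- file.path(dir, "ev.tsv")
  write_events_tsv(tim$timing, tsv)
  a <- read_stim_timing(paths, names(paths))
  b <- read_events_tsv(tsv, n_runs = 2)
  for (lab in names(a$classes)) {
    for (r in 1:2) {
      expect_equal(b$classes[[lab]][[r]]$onset, a$classes[[lab]][[r]]$onset,
                   tolerance = 1e-6)
    }
  }
})

test_that("events TSV requires onset/duration and keeps zero durations", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("onset\tduration\ttrial_type",
               "1.5\t0\tA", "8\t0\tA", "3\t2\tB"), p)
  ts <- read_events_tsv(p)
  expect_length(ts$classes, 2)
  expect_equal(ts$classes$A[[1]]$duration, c(0, 0))
  writeLines(c("start\tduration\ttrial_type", "1\t0\tA"), p)
  expect_error(read_events_tsv(p), "onset")
})

test_that("uvars dictionary is flat, sorted and round-trips", {
  p <- withr::local_tempfile(fileext = ".json")
  write_uvars(list(tr = 2.0, subj = "s1", n_volumes = 150L), p)
  r <- read_uvars(p)
  expect_identical(names(r), sort(names(r)))
  expect_equal(r$tr, 2)
  expect_identical(r$subj, "s1")
  expect_error(write_uvars(list(a = list(b = 1)), p), "flat")
})
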