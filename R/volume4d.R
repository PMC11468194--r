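#' 4D image time series
#'
#' The central container of the toolkit: a 3D+time intensity array together
#' with its spatial grid, repetition time, per-slice acquisition times and a
#' units tag that records what the values mean at each stage of processing
#' (`raw` signal, `percent` of baseline after scaling, `correlation`, `tsnr`
#' or `statistic`).  Run boundaries are carried as a vector of run lengths so
#' per-run operations (scaling, baseline polynomials, motion demeaning)
#' know where one acquisition ends and the next begins.
#'
#' @param data Numeric array, 3D (a single volume) or 4D (x, y, z, t).
#' @param grid A [make_grid()] object; defaults to unit voxels.
#' @param tr Repetition time in seconds.
#' @param slice_times Acquisition time of each z-slice within the TR
#'   (seconds, length nz, all in `[0, tr)`), or `numeric(0)` when unknown.
#' @param units One of `raw`, `percent`, `correlation`, `tsnr`, `statistic`.
#' @param runs Integer vector of run lengths summing to the number of
#'   volumes; default one run.
#' @return An object of class `volume4d`.
#' @examples
#' v <- volume4d(array(rnorm(8 * 8 * 4 * 10), c(8, 8, 4, 10)), tr = 2)
#' n_volumes(v)
#' @export
volume4d <- function(data, grid = NULL, tr = 1,
                     slice_times = numeric(0),
                     units = "raw", runs = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop2("data must be a 3D or 4D array")
  d <- dim(data)
  grid <- grid %||% make_grid(d[1:3])
  if (!identical(as.integer(d[1:3]), grid$dims))
    stop2("data dimensions %s do not match grid dims %s",
          paste(d[1:3], collapse = "x"), paste(grid$dims, collapse = "x"))
  if (!is.numeric(tr) || tr <= 0) stop2("tr must be positive seconds")
  if (length(slice_times)) {
    if (length(slice_times) != d[3])
      stop2("slice_times must have one entry per z-slice (%d)", d[3])
    if (any(slice_times < 0 | slice_times >= tr))
      stop2("slice_times must lie in [0, tr)")
  }
  units <- match.arg(units,
                     c("raw", "percent", "correlation", "tsnr", "statistic"))
  runs <- as.integer(runs %||% d[4])
  if (sum(runs) != d[4]) stop2("run lengths must sum to n_volumes")
  structure(list(data = data, grid = grid, tr = tr,
                 slice_times = as.numeric(slice_times),
                 units = units, runs = runs),
            class = "volume4d")
}

#' @rdname volume4d
#' @param vol A `volume4d`.
#' @export
n_volumes <- function(vol) dim(vol$data)[4]

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d %dx%dx%d x %d vols, TR %.4g s, units '%s', %d run(s)>\n",
              d[1], d[2], d[3], d[4], x$tr, x$units, length(x$runs)))
  invisible(x)
}

# Replace the data array, keeping (or overriding) metadata.
vol_with <- function(vol, data, ...) {
  upd <- list(...)
  out <- vol
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  out$data <- data
  for (nm in names(upd)) out[[nm]] <- upd[[nm]]
  out
}

# time x voxel matrix view (and back)
vol_as_tv <- function(vol) {
  d <- dim(vol$data)
  t(matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4]))
}

tv_as_vol <- function(mat, like) {
  d <- dim(like$data)
  vol_with(like, array(t(mat), dim = c(d[1:3], nrow(mat))))
}

#' Multi-echo acquisition set
#'
#' An ordered list of echoes acquired at strictly increasing echo times,
#' sharing one grid, TR and volume count.
#'
#' @param echoes List of [volume4d()] objects on an identical grid.
#' @param echo_times Echo times TE in ms, strictly increasing, one per echo.
#' @return Object of class `echo_set`.
#' @export
echo_set <- function(echoes, echo_times) {
  if (length(echoes) < 1L) stop2("echo_set needs at least one echo")
  if (length(echoes) != length(echo_times))
    stop2("one echo time per echo required")
  echo_times <- as.numeric(echo_times)
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0))
    stop2("echo_times must be positive and strictly increasing (ms)")
  ref <- echoes[[1]]
  for (e in echoes[-1]) {
    if (!grids_equal(e$grid, ref$grid) || n_volumes(e) != n_volumes(ref) ||
        abs(e$tr - ref$tr) > 1e-9)
      stop2("all echoes must share grid, volume count and TR")
  }
  structure(list(echoes = echoes, echo_times = echo_times),
            class = "echo_set")
}

#' Rigid-body motion parameter series
#'
#' Per-volume 6-parameter estimates in the fixed column order
#' (roll, pitch, yaw, dS, dL, dP): rotations in degrees about the z, x and
#' y world axes, then translations in mm along z (superior), x (left-right)
#' and y (posterior-anterior), matching the column layout of the standard
#' motion 1D files.
#'
#' @param params n x 6 numeric matrix (or coercible).
#' @param reference_index 1-based index of the registration reference
#'   volume; its row must be all zeros.
#' @return Object of class `motion_params` (an n x 6 matrix).
#' @export
motion_params <- function(params, reference_index = 1L) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop2("motion parameters must have 6 columns")
  colnames(params) <- c("roll", "pitch", "yaw", "dS", "dL", "dP")
  if (reference_index < 1L || reference_index > nrow(params))
    stop2("reference_index out of range")
  if (max(abs(params[reference_index, ])) > 1e-8)
    stop2("reference volume's motion parameters must be zero")
  structure(params, class = c("motion_params", "matrix"),
            reference_index = as.integer(reference_index))
}

#' Censor state of a time series
#'
#' Per-volume keep/censor flags together with the metrics that produced
#' them: the Euclidean norm of the motion-parameter first difference
#' (approximate mm) and the in-mask temporal outlier fraction.
#'
#' @param keep Logical vector, `TRUE` = volume retained.
#' @param enorm Per-volume Enorm values (first entry 0 by convention).
#' @param outlier_frac Per-volume outlier fractions in `[0, 1]`.
#' @param thresholds Named list or vector with `enorm` and `outliers`
#'   threshold values (NA = criterion disabled).
#' @return Object of class `censor_series`.
#' @export
censor_series <- function(keep, enorm = rep(0, length(keep)),
                          outlier_frac = rep(0, length(keep)),
                          thresholds = c(enorm = NA_real_,
                                         outliers = NA_real_)) {
  n <- length(keep)
  if (length(enorm) != n || length(outlier_frac) != n)
    stop2("censor components must all have length n_volumes")
  if (any(outlier_frac < 0 | outlier_frac > 1))
    stop2("outlier fractions must lie in [0, 1]")
  structure(list(keep = as.logical(keep), enorm = as.numeric(enorm),
                 outlier_frac = as.numeric(outlier_frac),
                 thresholds = thresholds),
            class = "censor_series")
}

#' Stimulus timing for one or more event classes
#'
#' @param classes Named list; each class is a list with one element per run,
#'   itself a list with numeric `onset` (non-decreasing, >= 0), `duration`
#'   (same length, `NA` where absent) and `modulators` (events x k matrix,
#'   possibly 0 columns).
#' @return Object of class `timing_set`.
#' @export
timing_set <- function(classes) {
  if (is.null(names(classes)) || any(names(classes) == ""))
    stop2("every stimulus class must be named")
  for (lab in names(classes)) {
    for (r in seq_along(classes[[lab]])) {
      ev <- classes[[lab]][[r]]
      if (length(ev$onset)) {
        if (any(ev$onset < 0)) stop2("class '%s' run %d: negative onset", lab, r)
        if (is.unsorted(ev$onset)) stop2("class '%s' run %d: onsets must be non-decreasing", lab, r)
        if (any(!is.na(ev$duration) & ev$duration < 0))
          stop2("class '%s' run %d: negative duration", lab, r)
      }
    }
  }
  structure(list(classes = classes), class = "timing_set")
}

n_runs <- function(ts) max(vapply(ts$classes, length, 1L))

#' Integer-labelled ROI/atlas volume
#'
#' @param grid A [make_grid()] object.
#' @param labels 3D array of non-negative integer labels on that grid.
#' @param label_table Named integer vector mapping label value -> region
#'   name (names hold the region names).
#' @return Object of class `roi_volume`.
#' @export
roi_volume <- function(grid, labels, label_table = NULL) {
  labels <- array(as.integer(labels), dim = grid$dims)
  if (any(labels < 0)) stop2("ROI labels must be non-negative")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (is.null(label_table))
    label_table <- setNames(present, paste0("roi_", present))
  missing <- setdiff(present, label_table)
  if (length(missing))
    stop2("labels present in data but absent from label_table: %s",
          paste(missing, collapse = ", "))
  structure(list(grid = grid, labels = labels, label_table = label_table),
            class = "roi_volume")
}
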