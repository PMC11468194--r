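# Physiological nuisance regressors: slicewise RETROICOR (cardiac and
# respiratory phase harmonics) and volumetric RVT (respiration volume per
# time) with shifted copies.

#' A sampled physiological trace
#'
#' @param samples Numeric series.
#' @param rate Sampling rate in Hz (> 0).
#' @param kind `"cardiac"` or `"respiratory"`.
#' @param start Offset in seconds of the first sample relative to the
#'   first retained EPI volume (negative = recording started earlier).
#' @return Object of class `physio_trace`.
#' @export
physio_trace <- function(samples, rate, kind, start = 0) {
  kind <- match.arg(kind, c("cardiac", "respiratory"))
  if (rate <= 0) stop2("sampling rate must be positive")
  structure(list(samples = as.numeric(samples), rate = rate, kind = kind,
                 start = start),
            class = "physio_trace")
}

#' Read a physiological trace file
#'
#' One-column text file; header comment lines `# rate <Hz>`,
#' `# kind <cardiac|respiratory>` and `# start <s>` carry the metadata.
#'
#' @param path File path.
#' @return A [physio_trace()].
#' @export
read_physio_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_meta <- function(key, default = NULL) {
    m <- grep(sprintf("^#\\s*%s\\s+", key), lines, value = TRUE)
    if (length(m)) trimws(sub(sprintf("^#\\s*%s\\s+", key), "", m[1]))
    else default
  }
  rate <- as.numeric(get_meta("rate") %||%
                       stop2("%s: missing '# rate <Hz>' header", path))
  kind <- get_meta("kind", "respiratory")
  start <- as.numeric(get_meta("start", "0"))
  physio_trace(read_column_file(path)[, 1], rate, kind, start)
}

#' Write a physiological trace file
#'
#' @param trace A [physio_trace()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_physio_trace <- function(trace, path) {
  writeLines(c(sprintf("# rate %s", fmt_num(trace$rate)),
               sprintf("# kind %s", trace$kind),
               sprintf("# start %s", fmt_num(trace$start)),
               format(trace$samples, digits = 10, trim = TRUE)), path)
  invisible(path)
}

#' Detect peaks and troughs of a physiological trace
#'
#' The trace is smoothed with a 0.25 s boxcar, strict local extrema are
#' located, extrema closer together than the kind-specific refractory
#' interval (0.3 s cardiac, 1.5 s respiratory) are thinned by keeping the
#' more extreme one, and a strictly alternating peak/trough sequence is
#' enforced by dropping the lesser of adjacent same-type extrema.
#'
#' @param trace A [physio_trace()].
#' @return List with integer `peaks` and `troughs` (sample indices).
#' @export
detect_extrema <- function(trace) {
  x <- trace$samples
  if (length(x) < 2 * trace$rate)
    stop2("trace must cover at least 2 s")
  if (max(x) - min(x) < 1e-12 * max(1, max(abs(x))))
    stop2("constant trace: no extrema")
  w <- max(1L, round(0.25 * trace$rate))
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  n <- length(sm)
  core <- 2:(n - 1)
  is_pk <- c(FALSE, sm[core] > sm[core - 1] & sm[core] >= sm[core + 1], FALSE)
  is_tr <- c(FALSE, sm[core] < sm[core - 1] & sm[core] <= sm[core + 1], FALSE)
  min_gap <- round((if (trace$kind == "cardiac") 0.3 else 1.5) * trace$rate)
  thin <- function(idx, want_max) {
    if (length(idx) < 2) return(idx)
    keep <- idx[1]
    for (i in idx[-1]) {
      last <- keep[length(keep)]
      if (i - last >= min_gap) keep <- c(keep, i)
      else if ((want_max && sm[i] > sm[last]) ||
               (!want_max && sm[i] < sm[last])) keep[length(keep)] <- i
    }
    keep
  }
  pk <- thin(which(is_pk), TRUE)
  tr <- thin(which(is_tr), FALSE)
  if (!length(pk) || !length(tr)) stop2("no extrema detected")
  # enforce strict alternation: among consecutive same-type extrema keep
  # the more extreme one
  ev <- rbind(data.frame(i = pk, type = 1), data.frame(i = tr, type = -1))
  ev <- ev[order(ev$i), ]
  keep <- rep(TRUE, nrow(ev))
  j <- 1
  for (k in seq_len(nrow(ev))[-1]) {
    if (ev$type[k] == ev$type[j]) {
      better <- if (ev$type[k] == 1) sm[ev$i[k]] > sm[ev$i[j]]
                else sm[ev$i[k]] < sm[ev$i[j]]
      if (better) { keep[j] <- FALSE; j <- k } else keep[k] <- FALSE
    } else j <- k
  }
  ev <- ev[keep, ]
  list(peaks = ev$i[ev$type == 1], troughs = ev$i[ev$type == -1])
}

# Cardiac phase: linear 0 -> 2*pi between successive peaks (periods
# extrapolated at the ends from the neighbouring interval).
cardiac_phase <- function(trace, peaks = NULL) {
  pk <- (peaks %||% detect_extrema(trace)$peaks)
  tpk <- (pk - 1) / trace$rate
  n <- length(trace$samples)
  tt <- (seq_len(n) - 1) / trace$rate
  if (length(tpk) < 2) stop2("need at least 2 cardiac peaks")
  per1 <- tpk[2] - tpk[1]; perN <- tpk[length(tpk)] - tpk[length(tpk) - 1]
  knots <- c(tpk[1] - per1, tpk, tpk[length(tpk)] + perN)
  idx <- findInterval(tt, knots, rightmost.closed = FALSE, all.inside = TRUE)
  2 * pi * (tt - knots[idx]) / (knots[idx + 1] - knots[idx])
}

# Respiratory phase: amplitude-histogram transform with sign from the
# derivative of the smoothed trace (phase in (-pi, pi], 0 at peak
# amplitude during inhalation... by convention phi = pi * F(r) * sign(dr/dt)
# with F the empirical amplitude CDF).
respiratory_phase <- function(trace) {
  x <- trace$samples
  w <- max(1L, round(0.25 * trace$rate))
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  Fr <- ecdf(sm)(sm)
  drv <- c(diff(sm), 0)
  sgn <- ifelse(drv >= 0, 1, -1)
  pi * Fr * sgn
}

#' Slicewise and volumetric physiological regressors
#'
#' An object holding the RETROICOR slicewise regressor array
#' (n_volumes x n_regressors x n_slices), the volumetric RVT matrix and
#' their labels.  With both cardiac and respiratory traces at the default
#' two harmonic orders there are `2 kinds x 2 (sin, cos) x 2 orders = 8`
#' slicewise regressors.
#'
#' @param slicewise n_volumes x k x n_slices array.
#' @param labels Labels for the slicewise regressors.
#' @param volumetric n_volumes x m matrix of RVT columns.
#' @param rvt_labels Labels for the RVT columns.
#' @return Object of class `physio_regressors`.
#' @export
physio_regressors <- function(slicewise, labels,
                              volumetric = matrix(0, dim(slicewise)[1], 0),
                              rvt_labels = character(0)) {
  if (dim(slicewise)[2] != length(labels))
    stop2("one label per slicewise regressor required")
  structure(list(slicewise = slicewise, labels = labels,
                 volumetric = volumetric, rvt_labels = rvt_labels),
            class = "physio_regressors")
}

#' Build slicewise RETROICOR regressors
#'
#' Computes cardiac phase (linear between successive heartbeats) and
#' respiratory phase (amplitude-histogram transform signed by the
#' derivative) and evaluates `sin(k phi)` and `cos(k phi)` for
#' `k = 1..orders` per trace, sampled at each slice's acquisition time
#' (volume onset + slice time).  With both traces at the default
#' `orders = 2` this yields 8 slicewise regressors.
#'
#' @param cardiac,resp [physio_trace()] objects (either may be `NULL`).
#' @param vol A [volume4d()] with slice timing present.
#' @param orders Number of harmonic orders (default 2).
#' @return A [physio_regressors()] (volumetric part empty; see
#'   [rvt_regressors()]).
#' @export
retroicor_regressors <- function(cardiac, resp, vol, orders = 2) {
  if (!length(vol$slice_times))
    stop2("RETROICOR needs slice timing on the EPI volume")
  nt <- n_volumes(vol)
  nz <- length(vol$slice_times)
  traces <- Filter(Negate(is.null), list(cardiac = cardiac, resp = resp))
  if (!length(traces)) stop2("at least one physiological trace is required")
  k <- 2 * orders * length(traces)
  out <- array(0, dim = c(nt, k, nz))
  labels <- character(0)
  col <- 0L
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    run_dur <- nt * vol$tr
    if (tr$start > 0 ||
        tr$start + length(tr$samples) / tr$rate < run_dur - vol$tr)
      stop2("%s trace does not cover the EPI run", nm)
    phi <- if (tr$kind == "cardiac") cardiac_phase(tr) else respiratory_phase(tr)
    for (ord in seq_len(orders)) {
      for (fun in c("sin", "cos")) {
        col <- col + 1L
        labels[col] <- sprintf("%s_%s%d", nm, fun, ord)
        f <- get(fun)
        for (z in seq_len(nz)) {
          tq <- (seq_len(nt) - 1) * vol$tr + vol$slice_times[z] - tr$start
          si <- clamp(round(tq * tr$rate) + 1, 1, length(phi))
          out[, col, z] <- f(ord * phi[si])
        }
      }
    }
  }
  physio_regressors(out, labels)
}

#' Respiration volume per time (RVT) regressors
#'
#' RVT is the breathing envelope (peak minus trough, linearly interpolated
#' across breaths) divided by the instantaneous breathing period,
#' interpolated to the volume acquisition times and demeaned.  One column
#' per requested shift is returned, each a delayed copy (edge-held) of the
#' unshifted series; the default five shifts of 0-20 s track the slow
#' vascular response to respiration-depth changes.
#'
#' @param resp A respiratory [physio_trace()].
#' @param vol A [volume4d()].
#' @param shifts_s Shifts in seconds (default `c(0, 5, 10, 15, 20)`).
#' @return n_volumes x length(shifts_s) matrix with shift labels.
#' @export
rvt_regressors <- function(resp, vol, shifts_s = c(0, 5, 10, 15, 20)) {
  ex <- detect_extrema(resp)
  if (length(ex$peaks) < 2 || length(ex$troughs) < 2)
    stop2("too few breaths to compute RVT")
  x <- resp$samples
  tt <- (seq_len(length(x)) - 1) / resp$rate
  tpk <- (ex$peaks - 1) / resp$rate
  ttr <- (ex$troughs - 1) / resp$rate
  env_hi <- approx(tpk, x[ex$peaks], tt, rule = 2)$y
  env_lo <- approx(ttr, x[ex$troughs], tt, rule = 2)$y
  period <- approx(tpk[-1], diff(tpk), tt, rule = 2)$y
  rvt <- (env_hi - env_lo) / period
  nt <- n_volumes(vol)
  tvol <- (seq_len(nt) - 1) * vol$tr - resp$start
  cols <- sapply(shifts_s, function(s)
    approx(tt, rvt, clamp(tvol - s, tt[1], tt[length(tt)]), rule = 2)$y)
  cols <- matrix(cols, nrow = nt)
  cols <- sweep(cols, 2, colMeans(cols))
  colnames(cols) <- sprintf("rvt_s%02d", as.integer(shifts_s))
  cols
}

#' Assemble the full physiological regressor set for the ricor block
#'
#' Convenience wrapper combining [retroicor_regressors()] (slicewise) and
#' [rvt_regressors()] (volumetric) into one [physio_regressors()] object
#' ready for [assemble_design()] or the ricor stage.
#'
#' @inheritParams retroicor_regressors
#' @inheritParams rvt_regressors
#' @return A [physio_regressors()].
#' @export
build_physio_regressors <- function(cardiac, resp, vol, orders = 2,
                                    shifts_s = c(0, 5, 10, 15, 20)) {
  slc <- retroicor_regressors(cardiac, resp, vol, orders)
  rvt <- if (!is.null(resp)) rvt_regressors(resp, vol, shifts_s)
         else matrix(0, n_volumes(vol), 0)
  physio_regressors(slc$slicewise, slc$labels, rvt,
                    colnames(rvt) %||% character(0))
}
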