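# Synthetic data with known ground truth: multi-echo EPI phantoms with
# injected motion, drift, task responses, physiological oscillations and
# spikes; quasi-periodic cardiac/respiratory traces; randomized task
# timing.  Every generator is deterministic given its seed, so all test
# fixtures are rebuilt from code.

phantom_defaults <- function() {
  list(
    dims = c(32L, 32L, 20L),
    voxel_size = c(3, 3, 4),     # mm, typical EPI
    tr = 2.2,                    # s
    n_volumes = 150L,
    runs = NULL,                 # run lengths; default single run
    n_echoes = 1L,
    echo_times = NULL,           # ms; default 30 (single) / 12.5,27.6,42.7
    slice_pattern = "seq",       # sequential ascending slice timing
    motion_amp = 1.0,            # max |rotation deg| and |translation mm|
    texture_pct = 10,            # smooth spatial texture sd, % of S0
    noise_pct = 1.25,            # Gaussian noise sd as % of baseline (TSNR ~ 80)
    drift_pct = 0.5,             # linear+quadratic drift amplitude, % baseline
    task = NULL,                 # list(timing=, betas_pct=named, basis=)
    cardiac_hz = NULL,           # planted cardiac oscillation
    resp_hz = NULL,
    physio_pct = 1.0,            # amplitude of planted oscillations, %
    spikes = NULL,               # list(volumes=, frac=, amp_sigma=)
    ghost = FALSE,               # add half-FOV ghost replica
    ghost_frac = 0.1,
    presteady = 0L,              # leading volumes scaled up (T1 saturation)
    presteady_scale = 1.10)
}

ellipsoid_dist <- function(dims, semi_frac = c(0.42, 0.42, 0.42)) {
  ctr <- (dims + 1) / 2
  ax <- dims * semi_frac
  x <- (seq_len(dims[1]) - ctr[1]) / ax[1]
  y <- (seq_len(dims[2]) - ctr[2]) / ax[2]
  z <- (seq_len(dims[3]) - ctr[3]) / ax[3]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  sqrt(r2)   # 1 at the ellipsoid surface
}

#' Generate a synthetic EPI phantom with known ground truth
#'
#' Builds an ellipsoidal three-shell "brain" (CSF rim, grey-matter shell,
#' white-matter core) with tissue-specific S0 and T2*, computes each
#' echo's signal as `S0 exp(-TE / T2*)`, then layers on, in order:
#' per-run polynomial drift, task responses at stated percent amplitudes
#' (sampled with the package's own HRF bases), physiological sinusoids
#' whose phase advances with each slice's acquisition time, multiplicative
#' spikes, leading pre-steady-state brightening, Gaussian noise, an
#' optional half-FOV ghost replica, and rigid motion injected with the
#' package's own resampler.  Everything injected is returned as ground
#' truth so recovery can be checked stage by stage.
#'
#' @param config Named list overriding the defaults (see Details in the
#'   package vignette); unknown names are an error.
#' @param seed Integer seed; the same seed reproduces the phantom exactly.
#' @return List of class `phantom` with `data` (a [volume4d()] or
#'   [echo_set()]), `truth` (tissue/S0/T2* arrays, brain mask, motion
#'   matrix, drift, task, physio, spike and noise descriptions) and the
#'   resolved `config`.
#' @export
make_phantom <- function(config = list(), seed = 1) {
  def <- phantom_defaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop2("unknown phantom config entries: %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  cfg$dims <- as.integer(cfg$dims)
  if (length(cfg$dims) != 3L || any(cfg$dims < 8L))
    stop2("phantom dims must be 3 integers >= 8")
  cfg$runs <- as.integer(cfg$runs %||% cfg$n_volumes)
  if (sum(cfg$runs) != cfg$n_volumes) stop2("run lengths must sum to n_volumes")
  if (is.null(cfg$echo_times))
    cfg$echo_times <- if (cfg$n_echoes > 1L) c(12.5, 27.6, 42.7)[seq_len(cfg$n_echoes)]
                      else 30
  set.seed(seed)
  d <- cfg$dims; nt <- cfg$n_volumes; nz <- d[3]
  grid <- make_grid(d, cfg$voxel_size)
  slice_times <- if (identical(cfg$slice_pattern, "none")) numeric(0)
                 else (seq_len(nz) - 1) / nz * cfg$tr

  # tissue shells from the ellipsoid distance map
  r <- ellipsoid_dist(d)
  tissue <- array(0L, d)
  tissue[r <= 1.0] <- 1L   # CSF rim
  tissue[r <= 0.85] <- 2L  # grey matter shell
  tissue[r <= 0.55] <- 3L  # white matter core
  s0_by <- c(0, 1600, 1000, 900)
  t2s_by <- c(NA, 90, 40, 50)         # ms
  s0 <- array(s0_by[tissue + 1L], d)
  t2star <- array(t2s_by[tissue + 1L], d)
  brain <- tissue > 0L
  if (cfg$texture_pct > 0) {
    # smooth random texture: gives the otherwise rotationally symmetric
    # ellipsoid registration features and left-right asymmetry
    tex <- array(rnorm(prod(d)), d)
    tvol_tmp <- volume4d(tex, grid = grid, tr = 1)
    tex <- gaussian_blur(tvol_tmp, 3 * mean(cfg$voxel_size))$data[, , , 1]
    tex <- tex / sd(tex[brain]) * cfg$texture_pct / 100
    s0 <- s0 * (1 + tex)
  }

  nv <- prod(d)
  tvol <- (seq_len(nt) - 1) * cfg$tr

  # shared multiplicative time courses (fractions of baseline)
  frac <- matrix(0, nt, nv)
  drift_coef <- NULL
  if (cfg$drift_pct > 0) {
    drift_coef <- matrix(0, length(cfg$runs), 2)
    dcol <- numeric(nt)
    for (ri in seq_along(run_index(cfg$runs))) {
      ix <- run_index(cfg$runs)[[ri]]
      x <- seq(-1, 1, length.out = length(ix))
      co <- runif(2, -1, 1) * cfg$drift_pct / 100
      drift_coef[ri, ] <- co
      dcol[ix] <- co[1] * x + co[2] * (1.5 * x^2 - 0.5)
    }
    frac <- frac + dcol   # recycled column-wise over voxels
  }

  task_truth <- NULL
  if (!is.null(cfg$task)) {
    ts <- cfg$task$timing
    betas <- cfg$task$betas_pct
    spec <- cfg$task$basis %||% basis_spec("GAM")
    tmask <- as.vector(cfg$task$mask %||% (tissue == 2L))
    zidx0 <- rep(seq_len(nz), each = d[1] * d[2])
    st0 <- if (length(slice_times)) slice_times else rep(0, nz)
    rix <- run_index(cfg$runs)
    for (lab in names(betas)) {
      runs_ev <- ts$classes[[lab]]
      for (z in seq_len(nz)) {
        vi <- which(zidx0 == z & tmask)
        if (!length(vi)) next
        resp <- numeric(nt)
        for (ri in seq_along(rix)) {
          ev <- if (ri <= length(runs_ev)) runs_ev[[ri]] else NULL
          if (is.null(ev) || !length(ev$onset)) next
          # responses evaluated at each slice's true acquisition time
          tt <- (seq_along(rix[[ri]]) - 1) * cfg$tr + st0[z]
          for (e in seq_along(ev$onset))
            resp[rix[[ri]]] <- resp[rix[[ri]]] +
              event_response(spec, tt - ev$onset[e], ev$duration[e])[, 1]
        }
        frac[, vi] <- frac[, vi] + (betas[[lab]] / 100) * resp
      }
    }
    task_truth <- list(timing = ts, betas_pct = betas, basis = spec,
                       mask = array(tmask, d))
  }

  physio_truth <- NULL
  if (!is.null(cfg$cardiac_hz) || !is.null(cfg$resp_hz)) {
    # phase advances with each slice's acquisition time; amplitude
    # strongest in the CSF rim, as for real pulsation
    amp <- array(0, d)
    amp[tissue == 1L] <- cfg$physio_pct / 100
    amp[tissue == 2L] <- 0.4 * cfg$physio_pct / 100
    ampv <- as.vector(amp)
    zidx <- rep(seq_len(nz), each = d[1] * d[2])
    phases <- list()
    for (f in c(cardiac = cfg$cardiac_hz, resp = cfg$resp_hz)) {
      ph0 <- runif(1, 0, 2 * pi)
      phases[[length(phases) + 1]] <- ph0
      st <- if (length(slice_times)) slice_times else rep(0, nz)
      for (z in seq_len(nz)) {
        vi <- which(zidx == z & ampv > 0)
        if (!length(vi)) next
        osc <- sin(2 * pi * f * (tvol + st[z]) + ph0)
        frac[, vi] <- frac[, vi] + outer(osc, ampv[vi])
      }
    }
    physio_truth <- list(cardiac_hz = cfg$cardiac_hz, resp_hz = cfg$resp_hz,
                         phases = unlist(phases), amp = amp)
  }

  if (cfg$presteady > 0L)
    frac[seq_len(cfg$presteady), ] <- frac[seq_len(cfg$presteady), ] +
      (cfg$presteady_scale - 1)

  spike_truth <- NULL
  if (!is.null(cfg$spikes)) {
    sp <- cfg$spikes
    vox_pool <- which(as.vector(brain))
    hit <- lapply(sp$volumes, function(v)
      sample(vox_pool, max(1, round((sp$frac %||% 0.1) * length(vox_pool)))))
    for (i in seq_along(sp$volumes))
      frac[sp$volumes[i], hit[[i]]] <- frac[sp$volumes[i], hit[[i]]] +
        (sp$amp_sigma %||% 10) * cfg$noise_pct / 100
    spike_truth <- list(volumes = sp$volumes, voxels = hit)
  }

  motion <- matrix(0, nt, 6)
  if (cfg$motion_amp > 0) {
    # smooth random walk, rescaled so each parameter stays within the amp
    for (j in 1:6) {
      w <- cumsum(rnorm(nt))
      w <- w - w[1]
      mx <- max(abs(w))
      if (mx > 0) motion[, j] <- w / mx * runif(1, 0.3, 1) * cfg$motion_amp
    }
  }

  build_echo <- function(te) {
    base <- as.vector(s0 * exp(-te / t2star))
    base[is.na(base)] <- 0
    sig <- (1 + frac) * rep(base, each = nt)
    if (cfg$ghost) {
      # N/2 ghost: half-FOV shifted replica along the phase axis (y)
      half <- d[2] %/% 2
      base3 <- array(base, d)
      ghost3 <- base3[, c((half + 1):d[2], 1:half), ]
      sig <- sig + cfg$ghost_frac * rep(as.vector(ghost3), each = nt)
    }
    if (cfg$noise_pct > 0) {
      ref <- mean(s0[brain]) * exp(-te / mean(t2star[brain], na.rm = TRUE))
      sig <- sig + matrix(rnorm(nt * nv, sd = cfg$noise_pct / 100 * ref),
                          nt, nv)
    }
    v <- volume4d(array(t(sig), dim = c(d, nt)), grid = grid, tr = cfg$tr,
                  slice_times = slice_times, runs = cfg$runs)
    if (cfg$motion_amp > 0) v <- apply_rigid_motion(v, motion)
    v
  }
  vols <- lapply(cfg$echo_times, build_echo)
  data <- if (length(vols) == 1L) vols[[1]] else echo_set(vols, cfg$echo_times)
  truth <- list(tissue = tissue, s0 = s0, t2star = t2star,
                brain_mask = brain, motion = motion,
                drift_coef = drift_coef, task = task_truth,
                physio = physio_truth, spikes = spike_truth,
                noise_pct = cfg$noise_pct, seed = seed)
  structure(list(data = data, truth = truth, config = cfg),
            class = "phantom")
}

#' Generate quasi-periodic cardiac and respiratory traces
#'
#' Beat/breath intervals are jittered around the nominal rates and the
#' amplitude is slowly modulated, which is enough structure for peak
#' detection and RVT to be exercised realistically.  Ground-truth peak
#' times are returned.
#'
#' @param duration_s Trace duration (should cover the EPI run).
#' @param rate Sampling rate in Hz.
#' @param cardiac_hz,resp_hz Nominal frequencies.
#' @param jitter Fractional sd of the interval jitter (0 = strictly
#'   periodic).
#' @param seed Integer seed.
#' @return List with `cardiac` and `resp` ([physio_trace()]) and `truth`
#'   (true peak times in seconds).
#' @export
make_physio_traces <- function(duration_s, rate = 50, cardiac_hz = 1.1,
                               resp_hz = 0.25, jitter = 0.05, seed = 1) {
  set.seed(seed)
  one <- function(f0, kind) {
    beats <- c(0)
    while (beats[length(beats)] < duration_s + 2 / f0) {
      iv <- (1 / f0) * max(0.4, 1 + jitter * rnorm(1))
      beats <- c(beats, beats[length(beats)] + iv)
    }
    tt <- seq(0, duration_s, by = 1 / rate)
    idx <- findInterval(tt, beats, all.inside = TRUE)
    phase <- 2 * pi * (tt - beats[idx]) / (beats[idx + 1] - beats[idx])
    am <- 1 + 0.1 * sin(2 * pi * 0.01 * tt + runif(1, 0, 2 * pi))
    samples <- am * cos(phase)   # peak exactly at each beat time
    list(trace = physio_trace(samples, rate, kind), peaks = beats[
      beats >= 0 & beats <= duration_s])
  }
  card <- one(cardiac_hz, "cardiac")
  resp <- one(resp_hz, "respiratory")
  list(cardiac = card$trace, resp = resp$trace,
       truth = list(cardiac_peaks = card$peaks, resp_peaks = resp$peaks))
}

#' Generate randomized task timing
#'
#' Draws event onsets with a minimum inter-onset gap, splits the requested
#' per-class event counts across runs, and (optionally) attaches random
#' durations and amplitude modulators.  When `dir` is given the timing is
#' also written as AFNI-style timing files and an equivalent events TSV.
#'
#' @param n_runs Number of runs.
#' @param run_len_s Run duration in seconds.
#' @param classes Named integer vector of per-class event counts (e.g.
#'   `c(task = 40, control = 24)`).
#' @param min_gap_s Minimum onset-to-onset gap (default 8 s).
#' @param durations Optional named list mapping class -> c(min, max)
#'   duration range in seconds.
#' @param modulators Attach a uniform(1, 3) amplitude modulator per event?
#' @param lead_s Dead time at the start of each run (default 10 s).
#' @param seed Integer seed.
#' @param dir Optional output directory for timing files.
#' @return List with `timing` ([timing_set()]) and `files` (named paths,
#'   empty when `dir` is `NULL`).
#' @export
make_task_timing <- function(n_runs, run_len_s, classes,
                             min_gap_s = 8, durations = NULL,
                             modulators = FALSE, lead_s = 10,
                             seed = 1, dir = NULL) {
  set.seed(seed)
  total <- sum(classes)
  per_run <- diff(round(seq(0, total, length.out = n_runs + 1)))
  usable <- run_len_s - lead_s - min_gap_s
  if (any(per_run * min_gap_s > usable))
    stop2("infeasible packing: %d events with %.3g s gaps exceed a %.3g s run",
          max(per_run), min_gap_s, run_len_s)
  class_of <- sample(rep(names(classes), classes))
  cls <- lapply(names(classes), function(l) vector("list", n_runs))
  names(cls) <- names(classes)
  ei <- 0L
  for (r in seq_len(n_runs)) {
    k <- per_run[r]
    # gap construction: sorted uniforms stretched over the slack
    slack <- usable - k * min_gap_s
    on <- lead_s + sort(runif(k)) * slack + min_gap_s * (seq_len(k) - 1)
    labs <- class_of[ei + seq_len(k)]
    ei <- ei + k
    for (l in names(classes)) {
      sel <- labs == l
      dur <- if (!is.null(durations[[l]]))
        runif(sum(sel), durations[[l]][1], durations[[l]][2])
      else rep(NA_real_, sum(sel))
      mods <- if (modulators) matrix(runif(sum(sel), 1, 3), ncol = 1)
              else matrix(0, sum(sel), 0)
      cls[[l]][[r]] <- list(onset = on[sel], duration = dur,
                            modulators = mods)
    }
  }
  ts <- timing_set(cls)
  files <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_stim_timing(ts, dir)
    tsv <- file.path(dir, "events.tsv")
    write_events_tsv(ts, tsv)
    files <- c(files, events_tsv = tsv)
  }
  list(timing = ts, files = files)
}
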