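# The regression block: HRF bases, event/nuisance/bandpass regressor
# construction, censoring, design assembly, GLM fitting (optionally with
# AR(1) prewhitening), general linear tests, degrees-of-freedom accounting
# and model warnings.

#' Specify an HRF basis
#'
#' Supported bases: `BLOCK(d)` and `dmUBLOCK` (boxcar convolved with the
#' incomplete-gamma impulse response `(t/4)^4 exp(4 - t)`, normalized so a
#' 1-s-duration response peaks at exactly 1 -- so longer events have larger
#' magnitude, in the units of the scaled regressor); `GAM(p, q)` (default
#' p = 8.6, q = 0.547, peak exactly 1 at `t = p q`); `SPMG1` (canonical
#' difference-of-gammas, peak-normalized); `TENT(b, c, n)` (n triangular
#' bases on knots evenly spaced over `[b, c]`; `CSPLIN` is accepted as an
#' alias).
#'
#' @param name Basis name.
#' @param duration Event duration in s for `BLOCK` (default 1).
#' @param p,q `GAM` shape parameters.
#' @param b,c,n `TENT` window start/end (s) and knot count (n >= 2).
#' @return Object of class `basis_spec`.
#' @export
basis_spec <- function(name, duration = 1, p = 8.6, q = 0.547,
                       b = 0, c = 12, n = 7) {
  name <- toupper(name)
  if (name == "CSPLIN") name <- "TENT"
  if (!name %in% c("BLOCK", "DMUBLOCK", "GAM", "SPMG1", "TENT"))
    stop2("unsupported basis '%s'", name)
  if (duration < 0) stop2("duration must be >= 0")
  if (name == "TENT" && (n < 2 || b >= c)) stop2("TENT needs n >= 2 and b < c")
  structure(list(name = name, duration = duration, p = p, q = q,
                 b = b, c = c, n = n), class = "basis_spec")
}

# integral of the BLOCK impulse response h(t) = (t/4)^4 exp(4 - t):
# H(t) = (24 e^4 / 256) * pgamma(t, 5)
block_H <- function(t) (24 * exp(4) / 256) * stats::pgamma(pmax(t, 0), 5)

block_unit_peak <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tt <- seq(0, 20, 0.001)
      cache <<- max(block_H(tt) - block_H(tt - 1))
    }
    cache
  }
})

# Response of the BLOCK family at times t for an event of duration d
# (d = 0 treated as an impulse scaled to the 1-s normalization).
block_response <- function(t, d) {
  if (d <= 0) {
    h <- ifelse(t > 0, (t / 4)^4 * exp(4 - t), 0)
    return(h / block_unit_peak())
  }
  (block_H(t) - block_H(t - d)) / block_unit_peak()
}

gam_response <- function(t, p, q) {
  ifelse(t > 0, (t / (p * q))^p * exp(p - t / q), 0)
}

spmg1_response <- local({
  norm <- NULL
  function(t) {
    h <- function(x) stats::dgamma(x, 6) - stats::dgamma(x, 16) / 6
    if (is.null(norm)) norm <<- max(h(seq(0, 32, 0.01)))
    ifelse(t > 0, h(t) / norm, 0)
  }
})

tent_response <- function(t, b, c, n) {
  knots <- seq(b, c, length.out = n)
  sp <- knots[2] - knots[1]
  sapply(knots, function(k) pmax(0, 1 - abs(t - k) / sp))
}

#' Sample an HRF basis on a regular time grid
#'
#' @param spec A [basis_spec()].
#' @param dt Sampling step in seconds (> 0).
#' @param length Duration of the sampled window in seconds.
#' @return List with `time` and a `values` matrix (time x n_basis).
#' @export
sample_basis <- function(spec, dt = 0.1, length = 32) {
  if (dt <= 0) stop2("dt must be positive")
  t <- seq(0, length, by = dt)
  v <- switch(spec$name,
              BLOCK = , DMUBLOCK = cbind(block_response(t, spec$duration)),
              GAM = cbind(gam_response(t, spec$p, spec$q)),
              SPMG1 = cbind(spmg1_response(t)),
              TENT = tent_response(t, spec$b, spec$c, spec$n))
  list(time = t, values = v)
}

basis_n_columns <- function(spec) if (spec$name == "TENT") spec$n else 1L

# Evaluate the per-event response of `spec` at times t (s relative to the
# event onset), honouring a per-event duration for the duration-modulated
# family.
event_response <- function(spec, t, duration = NA) {
  switch(spec$name,
         BLOCK = cbind(block_response(t, spec$duration)),
         DMUBLOCK = cbind(block_response(
           t, if (is.na(duration)) spec$duration else duration)),
         GAM = cbind(gam_response(t, spec$p, spec$q)),
         SPMG1 = cbind(spmg1_response(t)),
         TENT = tent_response(t, spec$b, spec$c, spec$n))
}

#' Build task regressors for one stimulus class
#'
#' Event responses are sampled at the volume acquisition times of each run
#' and combined according to `stim_type`: `time` sums events into one
#' column (or `n` columns for `TENT`); `AM1` scales each event's response
#' by its (first) modulator; `AM2` yields the unmodulated column plus one
#' column per modulator scaled by the modulator minus its within-class
#' event mean; `IM` gives each event its own column.  Per-event durations
#' reshape the response when the basis is `dmUBLOCK`.  Events starting at
#' or after the end of their run are dropped with a warning.
#'
#' @param ts A [timing_set()].
#' @param class_label Which class to build.
#' @param spec A [basis_spec()].
#' @param stim_type One of `time`, `AM1`, `AM2`, `IM`.
#' @param run_lengths Volumes per run.
#' @param tr Repetition time (s).
#' @return List with matrix `X` (sum(run_lengths) x k) and `labels`.
#' @export
event_regressors <- function(ts, class_label, spec, stim_type = "time",
                             run_lengths, tr) {
  stim_type <- match.arg(stim_type, c("time", "AM1", "AM2", "IM"))
  if (!class_label %in% names(ts$classes))
    stop2("unknown stimulus class '%s'", class_label)
  runs <- ts$classes[[class_label]]
  nb <- basis_n_columns(spec)
  # gather events across runs (drop events past run end)
  allmods <- do.call(rbind, lapply(runs, `[[`, "modulators"))
  nmod <- if (is.null(allmods)) 0L else ncol(allmods)
  if (stim_type %in% c("AM1", "AM2") && nmod < 1L)
    stop2("%s requires married modulators on class '%s'", stim_type, class_label)
  modmean <- if (nmod) colMeans(allmods) else numeric(0)
  n_im <- 0L
  cols <- list()
  total <- sum(run_lengths)
  offset <- 0L
  for (r in seq_along(run_lengths)) {
    nt <- run_lengths[r]
    tvol <- (seq_len(nt) - 1) * tr
    ev <- if (r <= length(runs)) runs[[r]] else empty_run()
    keep <- ev$onset < nt * tr
    if (any(!keep))
      warn2("class '%s' run %d: %d event(s) after run end dropped",
            class_label, r, sum(!keep))
    for (e in which(keep)) {
      resp <- event_response(spec, tvol - ev$onset[e], ev$duration[e])
      key <- switch(stim_type,
                    IM = {n_im <- n_im + 1L; sprintf("im%03d", n_im)},
                    "main")
      for (kb in seq_len(nb)) {
        kk <- if (nb > 1) sprintf("%s#%d", key, kb - 1) else key
        if (is.null(cols[[kk]])) cols[[kk]] <- numeric(total)
        amp <- if (stim_type == "AM1") ev$modulators[e, 1] else 1
        cols[[kk]][offset + seq_len(nt)] <-
          cols[[kk]][offset + seq_len(nt)] + amp * resp[, kb]
      }
      if (stim_type == "AM2") {
        for (j in seq_len(nmod)) {
          kk <- sprintf("amod%d", j)
          if (is.null(cols[[kk]])) cols[[kk]] <- numeric(total)
          cols[[kk]][offset + seq_len(nt)] <-
            cols[[kk]][offset + seq_len(nt)] +
            (ev$modulators[e, j] - modmean[j]) * resp[, 1]
        }
      }
    }
    offset <- offset + nt
  }
  if (!length(cols)) cols <- list(main = numeric(total))
  if (stim_type == "AM2") {
    for (j in seq_len(nmod)) {
      kk <- sprintf("amod%d", j)
      if (!is.null(cols[[kk]]) && max(abs(cols[[kk]])) < 1e-12)
        warn2("class '%s': modulator %d has zero variance; column is all zero",
              class_label, j)
    }
  }
  X <- do.call(cbind, cols)
  nice <- sub("^main$", class_label, names(cols))
  nice <- sub("^main#", paste0(class_label, "#"), nice)
  nice <- sub("^im", paste0(class_label, "#"), nice)
  nice <- sub("^amod", paste0(class_label, "_amt"), nice)
  list(X = X, labels = nice)
}

#' Bandpass filtering as nuisance regressors
#'
#' Builds, per run, sine/cosine columns at the DFT frequencies
#' `k / (N TR)` strictly outside the keep band `[fbot, ftop]` (band edges
#' belong to the keep band; the Nyquist frequency contributes a cosine
#' only; the constant term is owned by the baseline).  Projecting these
#' out inside the GLM is mathematically identical to FFT band rejection on
#' an uncensored run, while keeping the degrees-of-freedom cost explicit:
#' the predicted fractional loss is `1 - 2 TR (ftop - fbot)`.
#'
#' @param run_lengths Volumes per run.
#' @param tr Repetition time (s).
#' @param fbot,ftop Keep-band edges in Hz, `0 <= fbot < ftop <= Nyquist`.
#' @return List with block-diagonal matrix `X`, `labels`, and
#'   `dfloss_predicted` (fraction in `[0, 1]`).
#' @export
bandpass_regressors <- function(run_lengths, tr, fbot, ftop) {
  nyq <- 1 / (2 * tr)
  if (fbot < 0 || ftop <= fbot || ftop > nyq + 1e-12)
    stop2("keep band must satisfy 0 <= fbot < ftop <= Nyquist (%.4g Hz)", nyq)
  total <- sum(run_lengths)
  blocks <- list(); labels <- character(0)
  offset <- 0L
  eps <- 1e-9
  for (r in seq_along(run_lengths)) {
    nt <- run_lengths[r]
    tt <- seq_len(nt) - 1
    for (k in seq_len(nt %/% 2)) {
      f <- k / (nt * tr)
      if (f >= fbot - eps && f <= ftop + eps) next
      cosc <- numeric(total)
      cosc[offset + seq_len(nt)] <- cos(2 * pi * k * tt / nt)
      blocks <- c(blocks, list(cosc))
      labels <- c(labels, sprintf("bp_r%02d_c%04d", r, k))
      if (k * 2 != nt) {  # Nyquist sine is identically zero
        sinc <- numeric(total)
        sinc[offset + seq_len(nt)] <- sin(2 * pi * k * tt / nt)
        blocks <- c(blocks, list(sinc))
        labels <- c(labels, sprintf("bp_r%02d_s%04d", r, k))
      }
    }
    offset <- offset + nt
  }
  X <- if (length(blocks)) do.call(cbind, blocks) else matrix(0, total, 0)
  list(X = X, labels = labels,
       dfloss_predicted = 1 - 2 * tr * (ftop - fbot))
}

#' Motion nuisance regressors
#'
#' `demean` gives the six parameters centred to their per-run means;
#' `deriv` gives their backward first differences (first volume of each
#' run set to 0).  With `per_run`, each run gets its own block-diagonal
#' copy of the requested sets, which absorbs run-specific
#' motion-correlated variance.
#'
#' @param mp A [motion_params()] object.
#' @param types Subset of `c("demean", "deriv")`.
#' @param per_run Block-diagonal per-run expansion?
#' @param run_lengths Volumes per run.
#' @return List with matrix `X` and `labels`.
#' @export
motion_regressors <- function(mp, types = c("demean", "deriv"),
                              per_run = FALSE,
                              run_lengths = nrow(mp)) {
  bad <- setdiff(types, c("demean", "deriv"))
  if (length(bad)) stop2("unknown motion regressor type '%s'", bad[1])
  P <- unclass(mp)
  pn <- colnames(P)
  sets <- list()
  for (ty in types) {
    M <- matrix(0, nrow(P), 6, dimnames = list(NULL, pn))
    for (ix in run_index(run_lengths)) {
      if (ty == "demean") {
        M[ix, ] <- sweep(P[ix, , drop = FALSE], 2,
                         colMeans(P[ix, , drop = FALSE]))
      } else {
        M[ix, ] <- rbind(0, diff(P[ix, , drop = FALSE]))
      }
    }
    colnames(M) <- if (ty == "deriv") paste0(pn, "_dt") else pn
    sets <- c(sets, list(M))
  }
  X <- do.call(cbind, sets)
  if (per_run && length(run_lengths) > 1L) {
    blocks <- lapply(seq_along(run_lengths), function(r) {
      B <- X * 0
      ix <- run_index(run_lengths)[[r]]
      B[ix, ] <- X[ix, ]
      colnames(B) <- sprintf("%s_r%02d", colnames(X), r)
      B
    })
    X <- do.call(cbind, blocks)
  }
  list(X = X, labels = colnames(X))
}

#' Per-run polynomial baseline regressors
#'
#' Legendre polynomials of order 0..polort on each run's support,
#' orthonormalized on the sample grid (so the columns are exactly mutually
#' orthogonal within a run) and laid out block-diagonally across runs.
#' The automatic order rule is `polort = 1 + floor(run_duration_s / 150)`.
#'
#' @param run_lengths Volumes per run.
#' @param tr Repetition time (s).
#' @param polort Integer order >= 0, or `"auto"`.
#' @return List with matrix `X`, `labels`, and the resolved `polort` per
#'   run.
#' @export
baseline_regressors <- function(run_lengths, tr, polort = "auto") {
  total <- sum(run_lengths)
  blocks <- list(); labels <- character(0); orders <- integer(0)
  for (r in seq_along(run_lengths)) {
    nt <- run_lengths[r]
    po <- if (identical(polort, "auto")) 1 + floor(nt * tr / 150)
          else as.integer(polort)
    if (po < 0) stop2("polort must be >= 0")
    po <- as.integer(min(po, nt - 1L))
    orders[r] <- po
    x <- if (nt > 1) seq(-1, 1, length.out = nt) else 0
    P <- sapply(0:po, function(k) legendre_poly(x, k))
    P <- matrix(P, nrow = nt)
    Q <- qr.Q(qr(P))
    Q <- sweep(Q, 2, sign(diag(qr.R(qr(P)))), "*")  # constant column positive
    B <- matrix(0, total, po + 1)
    B[run_index(run_lengths)[[r]], ] <- Q
    blocks <- c(blocks, list(B))
    labels <- c(labels, sprintf("poly_r%02d_%d", r, 0:po))
  }
  list(X = do.call(cbind, blocks), labels = labels, polort = orders)
}

legendre_poly <- function(x, k) {
  if (k == 0) return(rep(1, length(x)))
  if (k == 1) return(x)
  pm1 <- rep(1, length(x)); p <- x
  for (m in 2:k) {
    pn <- ((2 * m - 1) * x * p - (m - 1) * pm1) / m
    pm1 <- p; p <- pn
  }
  p
}

#' Principal-component tissue regressors from an ROI
#'
#' Erodes the ROI by one voxel (to guard against partial-volume
#' contamination at tissue edges), then returns the top-k left singular
#' vectors of the demeaned in-ROI voxel-by-time matrix as unit-norm
#' nuisance columns (per run when `per_run`).
#'
#' @param vol A [volume4d()].
#' @param roi A [roi_volume()] on the same grid.
#' @param label ROI label (integer value or region name).
#' @param k Number of components.
#' @param per_run Compute per run (block-diagonal)?
#' @return List with matrix `X` and `labels`.
#' @export
roi_pc_regressors <- function(vol, roi, label, k = 3, per_run = FALSE) {
  val <- if (is.character(label)) {
    if (!label %in% names(roi$label_table)) stop2("unknown ROI label '%s'", label)
    roi$label_table[[label]]
  } else as.integer(label)
  sel <- roi$labels == val
  if (!any(sel)) stop2("ROI '%s' is empty", as.character(label))
  sel <- erode6(sel)
  if (!any(sel)) stop2("ROI '%s' vanished under one-voxel erosion",
                       as.character(label))
  Y <- vol_as_tv(vol)[, as.vector(sel), drop = FALSE]
  groups <- if (per_run) run_index(vol$runs) else list(seq_len(nrow(Y)))
  total <- nrow(Y)
  out <- list(); labels <- character(0)
  for (g in seq_along(groups)) {
    ix <- groups[[g]]
    Yr <- sweep(Y[ix, , drop = FALSE], 2, colMeans(Y[ix, , drop = FALSE]))
    sv <- svd(Yr, nu = min(k, length(ix)), nv = 0)
    rank <- sum(sv$d > max(sv$d) * 1e-10)
    kk <- min(k, rank)
    if (kk < k)
      warn2("ROI '%s': requested %d components but rank is %d",
            as.character(label), k, rank)
    for (j in seq_len(kk)) {
      col <- numeric(total)
      col[ix] <- sv$u[, j]
      out <- c(out, list(col))
      labels <- c(labels, if (per_run) sprintf("roipc%s_%d_r%02d",
                                               as.character(label), j, g)
                  else sprintf("roipc%s_%d", as.character(label), j))
    }
  }
  list(X = do.call(cbind, out), labels = labels)
}

#' Euclidean norm of the motion-parameter first difference
#'
#' `e[t] = || p_t - p_(t-1) ||_2` over the six parameters, with degrees and
#' mm combined unscaled (hence "approximate units of mm").  The first
#' volume of every run is 0: no difference is taken across run breaks.
#'
#' @param mp A [motion_params()] (or n x 6 matrix).
#' @param run_lengths Volumes per run.
#' @return Numeric vector, one value per volume.
#' @export
enorm_series <- function(mp, run_lengths = nrow(mp)) {
  P <- unclass(mp)
  e <- numeric(nrow(P))
  for (ix in run_index(run_lengths)) {
    if (length(ix) > 1)
      e[ix[-1]] <- sqrt(rowSums(diff(P[ix, , drop = FALSE])^2))
  }
  e
}

#' Build the censor series from motion and outlier criteria
#'
#' A volume is censored when its Enorm exceeds `enorm_thr` -- in which case
#' both flagged time points (t and t-1) are censored, since Enorm is a
#' difference measure -- or when its outlier fraction exceeds
#' `outlier_thr` (t only).  The criteria are combined by union; either may
#' be disabled with `NA`.
#'
#' @param enorm Per-volume Enorm values.
#' @param outlier_frac Per-volume outlier fractions.
#' @param enorm_thr Motion threshold (mm-equivalent), e.g. 0.3 for task
#'   data; `NA` disables.
#' @param outlier_thr Outlier-fraction threshold, e.g. 0.05; `NA` disables.
#' @return A [censor_series()].
#' @export
build_censor <- function(enorm, outlier_frac = rep(0, length(enorm)),
                         enorm_thr = 0.3, outlier_thr = 0.05) {
  n <- length(enorm)
  cen <- rep(FALSE, n)
  if (!is.na(enorm_thr)) {
    if (enorm_thr <= 0) stop2("enorm threshold must be positive")
    hit <- which(enorm > enorm_thr)
    cen[hit] <- TRUE
    cen[hit[hit > 1] - 1] <- TRUE
  }
  if (!is.na(outlier_thr)) {
    if (outlier_thr <= 0) stop2("outlier threshold must be positive")
    cen[outlier_frac > outlier_thr] <- TRUE
  }
  censor_series(keep = !cen, enorm = enorm, outlier_frac = outlier_frac,
                thresholds = c(enorm = enorm_thr, outliers = outlier_thr))
}

#' Assemble the full design matrix
#'
#' Concatenates category-tagged column sets into one labelled design.
#' Censored time points are removed from the solve by row deletion -- not
#' zero-weighting -- so bandpassing, censoring and regression happen as a
#' single mathematically consistent model; the censor series is retained
#' for reporting.
#'
#' @param parts Named list mapping a category (`baseline`, `motion`,
#'   `physio`, `bandpass`, `roi_pc`, or `stim:<label>`) to a list with
#'   `X` and `labels` (as produced by the regressor builders).  A
#'   `physio` entry may be slicewise (class `physio_regressors`), in which
#'   case its columns are substituted per slice at fit time.
#' @param censor Optional [censor_series()].
#' @param run_lengths Volumes per run.
#' @param tr Repetition time (s).
#' @return Object of class `design_matrix`.
#' @export
assemble_design <- function(parts, censor = NULL, run_lengths, tr) {
  total <- sum(run_lengths)
  X <- matrix(0, total, 0); labels <- character(0); category <- character(0)
  slicewise <- NULL
  for (cat in names(parts)) {
    p <- parts[[cat]]
    if (inherits(p, "physio_regressors")) {
      slicewise <- p
      if (dim(p$slicewise)[1] != total)
        stop2("slicewise regressors have %d rows, expected %d",
              dim(p$slicewise)[1], total)
      if (ncol(p$volumetric)) {
        X <- cbind(X, p$volumetric)
        labels <- c(labels, p$rvt_labels)
        category <- c(category, rep(cat, ncol(p$volumetric)))
      }
      next
    }
    if (is.matrix(p)) p <- list(X = p, labels = colnames(p))
    if (nrow(p$X) != total)
      stop2("category '%s' has %d rows, expected %d", cat, nrow(p$X), total)
    X <- cbind(X, p$X)
    labels <- c(labels, p$labels)
    category <- c(category, rep(cat, ncol(p$X)))
  }
  if (!is.null(slicewise)) {
    labels <- c(labels, slicewise$labels)
    category <- c(category, rep("physio", length(slicewise$labels)))
  }
  if (anyDuplicated(labels))
    stop2("duplicate design labels: %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (is.null(censor))
    censor <- censor_series(rep(TRUE, total))
  if (length(censor$keep) != total)
    stop2("censor length %d does not match %d volumes",
          length(censor$keep), total)
  colnames(X) <- labels[seq_len(ncol(X))]
  structure(list(X = X, labels = labels, category = category,
                 censor = censor, runs = as.integer(run_lengths), tr = tr,
                 slicewise = slicewise),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix %d volumes (%d censored) x %d columns>\n",
              nrow(x$X), sum(!x$censor$keep), length(x$labels)))
  print(table(x$category))
  invisible(x)
}

design_rank_check <- function(Xk, labels) {
  qx <- qr(Xk)
  if (qx$rank < ncol(Xk)) {
    dep <- labels[sort(qx$pivot[(qx$rank + 1):ncol(Xk)])]
    stop2("design is rank deficient; dependent columns: %s",
          paste(dep, collapse = ", "))
  }
  qx
}

# AR(1) prewhitening rows within runs (applied before censor-row deletion).
prewhiten_rows <- function(M, rho, run_lengths) {
  for (ix in run_index(run_lengths)) {
    W <- M[ix, , drop = FALSE]
    out <- W
    out[1, ] <- sqrt(1 - rho^2) * W[1, ]
    if (length(ix) > 1)
      out[-1, ] <- W[-1, , drop = FALSE] - rho * W[-length(ix), , drop = FALSE]
    M[ix, ] <- out
  }
  M
}

glm_solve <- function(Y, X, labels) {
  qx <- design_rank_check(X, labels)
  B <- qr.coef(qx, Y)
  R <- Y - X %*% B
  list(B = B, R = R, XtXinv = chol2inv(qr.R(qx)))
}

#' Fit the general linear model
#'
#' Ordinary (or AR(1)-prewhitened generalized) least squares per voxel:
#' betas, per-voxel residual variance with `df = rows - p`, t statistics
#' per beta, a full-model F against the baseline-only model, and the
#' residual (errts) series with censored time points zero-filled.  When
#' the design carries slicewise physiological regressors, each slice is
#' solved with its own physio columns substituted.  With
#' `whiten = "ar1"`, the lag-1 autocorrelation is estimated from pooled
#' first-pass residuals (runs handled separately), rows are prewhitened
#' with weights `(1, -rho)`, and the model refit.
#'
#' @param data A [volume4d()].
#' @param X A [assemble_design()] design.
#' @param whiten `"none"` or `"ar1"`.
#' @param mask Optional logical array: voxels used for pooling the AR(1)
#'   estimate (fits are always computed for the full field of view).
#' @return Object of class `glm_result`: `betas`/`se`/`tstat` (voxel x p
#'   matrices), `sigma2`, `fstat`, `df`, `rho`, `errts` ([volume4d()]),
#'   plus the design.
#' @export
fit_glm <- function(data, X, whiten = "none", mask = NULL) {
  whiten <- match.arg(whiten, c("none", "ar1"))
  keep <- X$censor$keep
  Y <- vol_as_tv(data)
  if (nrow(Y) != nrow(X$X))
    stop2("data has %d volumes but design has %d rows", nrow(Y), nrow(X$X))
  p_total <- length(X$labels)
  if (sum(keep) <= p_total)
    stop2("only %d retained rows for %d design columns", sum(keep), p_total)
  d <- dim(data$data)
  nz <- d[3]
  vox_slice <- rep(seq_len(nz), each = d[1] * d[2])
  maskv <- if (is.null(mask)) rep(TRUE, prod(d[1:3])) else as.vector(mask)

  fit_pass <- function(Yw, Xc, Xs) {
    B <- matrix(NA_real_, ncol(Xc) + ncol(Xs %||% matrix(0, 1, 0)), ncol(Yw))
    R <- matrix(NA_real_, nrow(Yw), ncol(Yw))
    covdiag <- matrix(NA_real_, nrow(B), ncol(Yw))
    if (is.null(Xs)) {
      s <- glm_solve(Yw, Xc, X$labels)
      B[] <- s$B; R[] <- s$R
      covdiag[] <- diag(s$XtXinv)
    } else {
      for (z in seq_len(nz)) {
        vi <- which(vox_slice == z)
        Xz <- cbind(Xc, Xs[, , z])
        s <- glm_solve(Yw[, vi, drop = FALSE], Xz, X$labels)
        B[, vi] <- s$B; R[, vi] <- s$R
        covdiag[, vi] <- diag(s$XtXinv)
      }
    }
    list(B = B, R = R, covdiag = covdiag)
  }

  prep <- function(Yw, Xw, Sw) {
    list(Y = Yw[keep, , drop = FALSE], X = Xw[keep, , drop = FALSE],
         S = if (is.null(Sw)) NULL else Sw[keep, , , drop = FALSE])
  }
  Xc <- X$X
  Sw <- if (is.null(X$slicewise)) NULL else X$slicewise$slicewise
  pr <- prep(Y, Xc, Sw)
  fit <- fit_pass(pr$Y, pr$X, pr$S)
  rho <- 0
  if (whiten == "ar1") {
    # pooled lag-1 autocorrelation of first-pass residuals over mask voxels
    Rfull <- matrix(0, nrow(Y), ncol(Y))
    Rfull[keep, ] <- fit$R
    num <- 0; den <- 0
    for (ix in run_index(X$runs)) {
      kix <- ix[keep[ix]]
      if (length(kix) < 3) next
      Rr <- Rfull[kix, maskv, drop = FALSE]
      num <- num + sum(Rr[-1, ] * Rr[-nrow(Rr), ])
      den <- den + sum(Rr^2)
    }
    rho <- if (den > 0) clamp(num / den, -0.95, 0.95) else 0
    Yw <- prewhiten_rows(Y, rho, X$runs)
    Xw <- prewhiten_rows(Xc, rho, X$runs)
    Sww <- Sw
    if (!is.null(Sw)) {
      for (z in seq_len(nz))
        Sww[, , z] <- prewhiten_rows(Sw[, , z, drop = FALSE][, , 1], rho, X$runs)
    }
    pr <- prep(Yw, Xw, Sww)
    fit <- fit_pass(pr$Y, pr$X, pr$S)
  }
  n_rows <- sum(keep)
  df <- n_rows - nrow(fit$B)
  sigma2 <- colSums(fit$R^2) / df
  se <- sqrt(fit$covdiag * rep(sigma2, each = nrow(fit$B)))
  tstat <- fit$B / se
  # full-model F against the baseline-only model
  bix <- which(X$category == "baseline")
  X0 <- pr$X[, bix, drop = FALSE]
  R0 <- if (ncol(X0)) pr$Y - X0 %*% qr.coef(qr(X0), pr$Y) else pr$Y
  p1 <- nrow(fit$B); p0 <- length(bix)
  rss0 <- colSums(R0^2); rss1 <- colSums(fit$R^2)
  fstat <- pmax(0, ((rss0 - rss1) / (p1 - p0)) / (rss1 / df))
  fstat[!is.finite(fstat)] <- 0  # constant voxels (e.g. outside the FOV)
  # errts on the original grid: censored rows zero-filled
  E <- matrix(0, nrow(Y), ncol(Y))
  E[keep, ] <- fit$R
  errts <- tv_as_vol(E, data)
  structure(list(betas = t(fit$B), se = t(se), tstat = t(tstat),
                 labels = X$labels, sigma2 = sigma2, fstat = fstat,
                 df = df, rho = rho, errts = errts, design = X,
                 dims = d[1:3]),
            class = "glm_result")
}

#' General linear test of stimulus effects
#'
#' Evaluates `w' beta` per voxel for a single weight vector (t statistic)
#' or an F test for a multi-row weight set, e.g. a `Task - Control`
#' contrast or the mean `0.5 (Task + Control)` response.
#'
#' @param res A [fit_glm()] result.
#' @param weights Named numeric vector (names = design labels), or a
#'   matrix with one test per row and labelled columns.
#' @param label Name for the test.
#' @return List with `label`, `estimate` (voxel vector; first row's
#'   estimate for F tests), `stat`, `stat_type` (`"t"` or `"F"`), `df`.
#' @export
linear_test <- function(res, weights, label = "GLT") {
  W <- if (is.matrix(weights)) weights else matrix(weights, nrow = 1,
                                                   dimnames = list(NULL, names(weights)))
  if (is.null(colnames(W))) stop2("weights must be labelled")
  unknown <- setdiff(colnames(W), res$labels)
  if (length(unknown))
    stop2("weights reference unknown columns: %s", paste(unknown, collapse = ", "))
  if (max(abs(W)) == 0) stop2("all-zero weight set")
  Wfull <- matrix(0, nrow(W), length(res$labels),
                  dimnames = list(NULL, res$labels))
  Wfull[, colnames(W)] <- W
  est <- res$betas %*% Wfull[1, ]
  X <- res$design
  keep <- X$censor$keep
  Xk <- X$X[keep, , drop = FALSE]
  # covariance restricted to the common (non-slicewise) columns
  Wc <- Wfull[, seq_len(ncol(Xk)), drop = FALSE]
  XtXinv <- chol2inv(qr.R(qr(Xk)))
  if (nrow(W) == 1L) {
    v <- drop(Wc %*% XtXinv %*% t(Wc))
    stat <- drop(res$betas[, seq_len(ncol(Xk)), drop = FALSE] %*% t(Wc)) /
      sqrt(v * res$sigma2)
    list(label = label, estimate = drop(est), stat = stat,
         stat_type = "t", df = res$df)
  } else {
    Vw <- Wc %*% XtXinv %*% t(Wc)
    Bw <- res$betas[, seq_len(ncol(Xk)), drop = FALSE] %*% t(Wc)
    qf <- rowSums((Bw %*% solve(Vw)) * Bw)
    stat <- (qf / nrow(W)) / res$sigma2
    list(label = label, estimate = drop(est), stat = stat,
         stat_type = "F", df = c(nrow(W), res$df))
  }
}

#' Degrees-of-freedom ledger
#'
#' Exact bookkeeping of where the time series' degrees of freedom go:
#' total volumes, censored volumes, per-category regressor counts, and
#' what remains.  Warning flags are raised when fewer than 30 percent of
#' the DFs remain (warn) or none do (error-level).
#'
#' @param X A [assemble_design()] design.
#' @return Object of class `df_ledger` with fields `n_total`,
#'   `n_censored`, `used` (named per-category counts), `df_remaining`,
#'   `fractions`, `flag` (`none`/`warn`/`error`).
#' @export
compute_df_ledger <- function(X) {
  n_total <- nrow(X$X)
  n_censored <- sum(!X$censor$keep)
  used <- vapply(split(X$labels, X$category), length, 1L)
  remaining <- n_total - n_censored - sum(used)
  fractions <- c(censored = n_censored, used,
                 remaining = remaining) / n_total
  flag <- if (remaining <= 0) "error"
          else if (remaining / n_total < 0.30) "warn" else "none"
  structure(list(n_total = n_total, n_censored = n_censored, used = used,
                 df_remaining = remaining, fractions = fractions,
                 flag = flag),
            class = "df_ledger")
}

#' @export
print.df_ledger <- function(x, ...) {
  cat(sprintf("DF ledger: %d total | %d censored | %s | %d remaining (%.1f%%)%s\n",
              x$n_total, x$n_censored,
              paste(sprintf("%s %d", names(x$used), x$used), collapse = " | "),
              x$df_remaining, 100 * x$df_remaining / x$n_total,
              if (x$flag != "none") paste0(" [", toupper(x$flag), "]") else ""))
  invisible(x)
}

#' Automatic model design warnings
#'
#' Checks the assembled model for: (a) collinearity among stimulus
#' columns (|r| > 0.4 medium, > 0.7 severe); (b) a high overall censor
#' fraction (> 0.1 medium); (c) stimulus classes whose events mostly
#' overlap censored volumes (> 0.5 of events, severe); (d) unremoved
#' pre-steady-state volumes; (e) degrees-of-freedom overuse from the
#' ledger.
#'
#' @param X A [assemble_design()] design.
#' @param ts Optional [timing_set()] for the per-class censor-overlap
#'   check.
#' @param presteady_count Leading pre-steady-state volumes still present
#'   (from [detect_pre_steady_state()] minus the removed count).
#' @param response_window Seconds after onset considered part of an
#'   event's response (default 12 plus the event duration).
#' @return Data frame with columns `check`, `level`, `message`; zero rows
#'   when the design is clean.
#' @export
design_warnings <- function(X, ts = NULL, presteady_count = 0,
                            response_window = 12) {
  out <- list()
  add <- function(check, level, msg)
    out[[length(out) + 1]] <<- data.frame(check = check, level = level,
                                          message = msg)
  keep <- X$censor$keep
  six <- which(startsWith(X$category, "stim"))
  if (length(six) >= 2) {
    S <- X$X[keep, six, drop = FALSE]
    ok <- apply(S, 2, sd) > 0
    if (sum(ok) >= 2) {
      C <- cor(S[, ok, drop = FALSE])
      mx <- max(abs(C[upper.tri(C)]))
      if (mx > 0.4)
        add("stim_collinearity", if (mx > 0.7) "severe" else "medium",
            sprintf("max |r| between stimulus regressors = %.3f", mx))
    }
  }
  cfrac <- mean(!keep)
  if (cfrac > 0.1)
    add("censor_fraction", "medium",
        sprintf("%.1f%% of volumes censored", 100 * cfrac))
  if (!is.null(ts)) {
    runs <- X$runs
    starts <- cumsum(c(0, head(runs, -1)))
    cens_t <- (which(!keep) - 1) * X$tr
    run_of <- rep(seq_along(runs), runs)[which(!keep)]
    for (lab in names(ts$classes)) {
      tot <- 0L; hit <- 0L
      for (r in seq_along(ts$classes[[lab]])) {
        ev <- ts$classes[[lab]][[r]]
        for (e in seq_along(ev$onset)) {
          tot <- tot + 1L
          dur <- if (is.na(ev$duration[e])) 0 else ev$duration[e]
          lo <- ev$onset[e]; hi <- ev$onset[e] + dur + response_window
          ct <- cens_t[run_of == r] - starts[r] * X$tr
          if (any(ct >= lo & ct <= hi)) hit <- hit + 1L
        }
      }
      if (tot > 0 && hit / tot > 0.5)
        add("stim_censor_overlap", "severe",
            sprintf("class '%s': %d of %d events overlap censoring",
                    lab, hit, tot))
    }
  }
  if (presteady_count > 0)
    add("pre_steady_state", "medium",
        sprintf("%d apparent pre-steady-state volume(s) not removed",
                presteady_count))
  ledger <- compute_df_ledger(X)
  if (ledger$flag != "none")
    add("df_remaining", if (ledger$flag == "error") "severe" else "medium",
        sprintf("only %d of %d DFs remain", ledger$df_remaining,
                ledger$n_total))
  if (!length(out))
    return(data.frame(check = character(0), level = character(0),
                      message = character(0)))
  do.call(rbind, out)
}
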