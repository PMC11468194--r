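# Quality-control battery: scalar metrics, derived maps, alignment cost and
# left-right flip checking, ROI shape/TSNR tables, the basic review text,
# cross-subject review tables and the static HTML report.
#
# QC maps are deliberately computed over the whole field of view: the brain
# mask is used only to summarize, never multiplied into the data, so
# ghosts, spikes and other artifacts outside the brain stay visible.

#' Temporal signal-to-noise ratio map
#'
#' Per voxel: mean of the baseline-fitted signal divided by the standard
#' deviation of the residual, computed over the whole FOV.  When a
#' residual series is supplied (e.g. the errts output of [fit_glm()]) it
#' provides the noise term; otherwise the per-run baseline polynomial
#' detrend is used for both parts.  Voxels with zero residual sd get
#' TSNR 0 by convention, and negative ratios are clamped to 0.
#'
#' @param vol A [volume4d()] with >= 10 volumes.
#' @param residuals Optional [volume4d()] of model residuals.
#' @param mask Optional logical array; used only for the `mean_in_mask`
#'   attribute, not to restrict the map.
#' @return `volume4d` (single volume, units `tsnr`) with attribute
#'   `mean_in_mask` when a mask is given.
#' @export
tsnr_map <- function(vol, residuals = NULL, mask = NULL) {
  if (n_volumes(vol) < 10L) stop2("TSNR needs at least 10 volumes")
  Y <- vol_as_tv(vol)
  R <- detrend_residuals(Y, vol$runs, vol$tr)
  base_mean <- colMeans(Y - R)
  noise <- if (is.null(residuals)) R else vol_as_tv(residuals)
  sdn <- apply(noise, 2, sd)
  # numerically-constant series count as zero-noise -> TSNR 0
  flat <- sdn <= 1e-8 * pmax(abs(base_mean), .Machine$double.eps)
  tsnr <- ifelse(sdn > 0 & !flat, pmax(0, base_mean / sdn), 0)
  out <- volume4d(array(tsnr, dim = vol$grid$dims), grid = vol$grid,
                  tr = vol$tr, units = "tsnr")
  if (!is.null(mask))
    attr(out, "mean_in_mask") <- mean(tsnr[as.vector(mask)])
  out
}

#' Radial correlation map
#'
#' Correlates each voxel's time series with the Gaussian-weighted average
#' of the surrounding voxels' series over a large radius (default 20 mm
#' half width at half maximum).  Coherent blobs of high correlation far
#' outside the brain, or stripes, reveal scanner or motion artifacts.
#'
#' @param vol A [volume4d()] with >= 10 volumes.
#' @param hwhm_mm Gaussian HWHM of the neighbourhood weighting in mm.
#' @return `volume4d` (single volume, units `correlation`).
#' @export
radial_correlation <- function(vol, hwhm_mm = 20) {
  if (n_volumes(vol) < 10L) stop2("radial correlation needs >= 10 volumes")
  nb <- gaussian_blur(vol, fwhm_mm = 2 * hwhm_mm)
  r <- rowwise_correlation(vol_as_tv(vol), vol_as_tv(nb))
  volume4d(array(r, vol$grid$dims), grid = vol$grid, tr = vol$tr,
           units = "correlation")
}

# Pearson correlation of corresponding columns of two time x voxel
# matrices (0 where either series is constant).
rowwise_correlation <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  den <- sqrt(colSums(A^2) * colSums(B^2))
  ifelse(den > 0, colSums(A * B) / den, 0)
}

#' Global correlation (GCOR)
#'
#' The average of the full voxel-pair correlation matrix over the mask,
#' computed as the squared norm of the mean of the demeaned, unit-norm
#' voxel series.  Always in `[0, 1]`; high values flag globally coherent
#' artifacts (motion residuals, breathing).
#'
#' @param vol A [volume4d()].
#' @param mask Logical array with at least 2 in-mask voxels.
#' @return Scalar in `[0, 1]`.
#' @export
gcor <- function(vol, mask) {
  Y <- vol_as_tv(vol)[, as.vector(mask), drop = FALSE]
  if (ncol(Y) < 2L) stop2("GCOR needs at least 2 in-mask voxels")
  Y <- sweep(Y, 2, colMeans(Y))
  nrm <- sqrt(colSums(Y^2))
  ok <- nrm > 0
  if (!any(ok)) stop2("all in-mask series are constant")
  U <- sweep(Y[, ok, drop = FALSE], 2, nrm[ok], "/")
  sum(rowMeans(U)^2)
}

#' Correlation map with an ROI-average (or global) time series
#'
#' Correlates every voxel in the FOV with the mean series over all
#' nonzero-label voxels of the reference.  With the brain mask as the
#' reference this is the classic corr_brain map.
#'
#' @param vol A [volume4d()].
#' @param roi A [roi_volume()] or a logical mask array.
#' @return `volume4d` (single volume, units `correlation`).
#' @export
average_roi_correlation_map <- function(vol, roi) {
  sel <- if (inherits(roi, "roi_volume")) as.vector(roi$labels > 0)
         else as.vector(roi)
  if (!any(sel)) stop2("reference region is empty")
  Y <- vol_as_tv(vol)
  ref <- rowMeans(Y[, sel, drop = FALSE])
  r <- rowwise_correlation(Y, matrix(ref, nrow(Y), ncol(Y)))
  volume4d(array(r, vol$grid$dims), grid = vol$grid, tr = vol$tr,
           units = "correlation")
}

#' Default QC seed locations
#'
#' When a template space is declared, three shipped template-space seeds
#' are used (posterior-cingulate/default-mode, visual, auditory, in mm).
#' Otherwise two central but left-right offset seeds are placed at
#' one-quarter of the field of view either side of the midline.
#'
#' @param grid The final-space [make_grid()].
#' @param template Template-space name or `NULL`.
#' @return Named list of world-mm coordinate triples.
#' @export
default_seed_locations <- function(grid, template = NULL) {
  if (!is.null(template)) {
    return(list(dmn = c(0, -52, 26), visual = c(2, -82, 4),
                auditory = c(-54, -14, 8)))
  }
  ctr <- grid_center_world(grid)
  off <- grid$voxel_size[1] * grid$dims[1] / 4
  list(seed_left = ctr - c(off, 0, 0), seed_right = ctr + c(off, 0, 0))
}

#' Seed-based correlation map
#'
#' Correlates every voxel with the series of the voxel nearest the given
#' world-mm seed, excluding censored volumes from the correlation.
#'
#' @param vol A [volume4d()].
#' @param seed_xyz World-mm coordinate triple.
#' @param censor Optional [censor_series()].
#' @return `volume4d` (units `correlation`).
#' @export
seed_correlation_map <- function(vol, seed_xyz, censor = NULL) {
  ijk <- round(grid_world_to_voxel(vol$grid, seed_xyz))
  if (any(ijk < 0) || any(ijk >= vol$grid$dims))
    stop2("seed (%.1f, %.1f, %.1f) mm falls outside the FOV",
          seed_xyz[1], seed_xyz[2], seed_xyz[3])
  keep <- if (is.null(censor)) rep(TRUE, n_volumes(vol)) else censor$keep
  Y <- vol_as_tv(vol)[keep, , drop = FALSE]
  sv <- 1 + ijk[1] + vol$grid$dims[1] * (ijk[2] + vol$grid$dims[2] * ijk[3])
  r <- rowwise_correlation(Y, matrix(Y[, sv], nrow(Y), ncol(Y)))
  volume4d(array(r, vol$grid$dims), grid = vol$grid, tr = vol$tr,
           units = "correlation")
}

#' Local Pearson correlation alignment cost
#'
#' Partitions the FOV into cubic patches of roughly `patch_mm` edge,
#' computes the Pearson correlation of the two images within each patch
#' with sufficient variance, and returns the voxel-count-weighted mean of
#' `-rho * |rho|`.  Identical images score -1 and contrast-reversed pairs
#' +1, which makes the cost suitable for aligning images of opposite
#' tissue contrast (EPI vs T1w).
#'
#' @param a,b 3D arrays on the same grid.
#' @param grid Their [make_grid()].
#' @param patch_mm Approximate patch edge in mm.
#' @return Scalar cost in `[-1, 1]`.
#' @export
lpc_cost <- function(a, b, grid, patch_mm = 8) {
  if (!identical(dim(a), dim(b))) stop2("images must share a grid")
  d <- dim(a)
  np <- pmax(1L, round(patch_mm / grid$voxel_size))
  bins <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1) %/% np[ax])
  pid <- as.vector(
    bins[[1]][slice.index(a, 1)] +
      (max(bins[[1]]) + 1) * (bins[[2]][slice.index(a, 2)] +
      (max(bins[[2]]) + 1) * bins[[3]][slice.index(a, 3)]))
  av <- as.vector(a); bv <- as.vector(b)
  num <- 0; den <- 0
  for (g in split(seq_along(pid), pid)) {
    if (length(g) < 4) next
    x <- av[g]; y <- bv[g]
    if (sd(x) < 1e-12 || sd(y) < 1e-12) next
    rho <- cor(x, y)
    w <- length(g)
    num <- num + w * rho * abs(rho)
    den <- den + w
  }
  if (den == 0) stop2("no patch with sufficient variance")
  -num / den
}

# flip an array left-right (first axis)
mirror_x <- function(arr) arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE]

align_cost_search <- function(epi, anat, grid, patch_mm = 8) {
  obj <- function(p) {
    A <- rigid_affine(c(0, 0, p[4], p[3], p[1], p[2]),
                      grid_center_world(grid))
    lpc_cost(epi, resample_volume(anat, grid, grid, A, "trilinear"),
             grid, patch_mm)
  }
  fit <- optim(c(0, 0, 0, 0), obj, method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-6))
  fit$value
}

#' Left-right flip check between EPI and anatomical volumes
#'
#' Aligns the anatomical and its x-mirrored copy to the EPI reference with
#' a small rigid search under the local Pearson correlation cost and
#' compares the best costs.  A data-entry error that flips one of the two
#' left-right shows up as the mirrored copy aligning better.
#'
#' @param epi_ref 3D array (EPI reference volume).
#' @param anat 3D array on the same grid.
#' @param grid Their [make_grid()].
#' @param margin Cost-difference margin below which the check is
#'   `inconclusive` (default 0.02; a perfectly symmetric brain ties).
#' @return List with `verdict` (`no_flip`, `flip_suspected`,
#'   `inconclusive`), `cost_as_is`, `cost_flipped`.
#' @export
left_right_flip_check <- function(epi_ref, anat, grid, margin = 0.02) {
  c0 <- align_cost_search(epi_ref, anat, grid)
  c1 <- align_cost_search(epi_ref, mirror_x(anat), grid)
  verdict <- if (c0 < c1 - margin) "no_flip"
             else if (c1 < c0 - margin) "flip_suspected"
             else "inconclusive"
  list(verdict = verdict, cost_as_is = c0, cost_flipped = c1)
}

# erosion depth of every true voxel (1 = removed by first erosion)
erosion_depth <- function(mask) {
  depth <- array(0L, dim(mask))
  cur <- mask
  k <- 0L
  while (any(cur)) {
    k <- k + 1L
    nxt <- erode6(cur)
    depth[cur & !nxt] <- k
    cur <- nxt
    if (k > max(dim(mask))) break
  }
  depth
}

#' TSNR and shape statistics per ROI
#'
#' For each requested region: voxel count (Nvox), count of zero-TSNR
#' voxels (Nzer), maximum 6-connected erosion depth in voxels (Dvox, a
#' narrowness measure), the TSNR five-number summary over nonzero voxels,
#' and the coordinates of the deepest voxel.  Warnings flag empty or
#' narrow shapes (Nzer > 0 or Dvox <= 1) and low TSNR (median below half
#' the global median).
#'
#' @param tsnr A TSNR [volume4d()] (single volume).
#' @param roi A [roi_volume()] on the same grid.
#' @param labels Integer label values, region names, or `"ALL"`.
#' @return Data frame, one row per ROI.
#' @export
roi_stats_table <- function(tsnr, roi, labels = "ALL") {
  tv <- tsnr$data[, , , 1]
  vals <- if (identical(labels, "ALL")) roi$label_table
          else sapply(labels, function(l) {
            if (is.character(l)) {
              if (!l %in% names(roi$label_table))
                stop2("unknown ROI label '%s'", l)
              roi$label_table[[l]]
            } else {
              if (!l %in% roi$label_table) stop2("unknown ROI label '%s'", l)
              as.integer(l)
            }
          })
  if (is.null(names(vals)))
    names(vals) <- names(roi$label_table)[match(vals, roi$label_table)]
  glob_med <- median(tv[roi$labels > 0 & tv > 0])
  rows <- lapply(names(vals), function(nm) {
    sel <- roi$labels == vals[[nm]]
    nv <- sum(sel)
    nz <- sum(tv[sel] == 0)
    dep <- erosion_depth(sel)
    dvox <- max(dep)
    peak <- which(dep == dvox, arr.ind = TRUE)[1, ] - 1L
    tq <- if (nv - nz > 0) quantile(tv[sel & tv > 0], c(0, .25, .5, .75, 1))
          else rep(NA_real_, 5)
    warn <- c(if (nz > 0 || dvox <= 1) "shape",
              if (!is.na(tq[3]) && !is.na(glob_med) && tq[3] < glob_med / 2)
                "low_tsnr")
    data.frame(label = nm, value = vals[[nm]], Nvox = nv, Nzer = nz,
               Dvox = dvox, Tmin = tq[1], T25 = tq[2], Tmed = tq[3],
               T75 = tq[4], Tmax = tq[5],
               peak_x = peak[1], peak_y = peak[2], peak_z = peak[3],
               warns = paste(warn, collapse = ";"))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Detect through-plane variance lines
#'
#' Scanner artifacts sometimes appear as (x, y) columns of high temporal
#' variance running through the slices.  For every in-mask column the
#' mean detrended temporal variance is computed; columns exceeding the
#' robust centre + 4 MADN of the column-variance distribution are
#' flagged.  The test is a ratio against the distribution, so it is
#' invariant to global intensity scaling.
#'
#' @param vol A [volume4d()] with nz >= 4.
#' @param mask Logical array.
#' @return Data frame of flagged 0-based `x`, `y` columns (possibly empty).
#' @export
variance_line_check <- function(vol, mask) {
  d <- vol$grid$dims
  if (d[3] < 4L) stop2("variance line check needs nz >= 4")
  R <- detrend_residuals(vol_as_tv(vol), vol$runs, vol$tr)
  v <- colSums(R^2) / (nrow(R) - 1)
  vv <- array(v, d); mm <- array(as.vector(mask), d)
  vv[!mm] <- NA
  # per-(x,y) column: median in-mask voxel variance (robust to columns
  # that graze the mask edge)
  colvar <- apply(vv, c(1, 2), median, na.rm = TRUE)
  ncol_in <- apply(mm, c(1, 2), sum)
  use <- ncol_in > d[3] / 2
  cv <- colvar[use]
  thr <- median(cv) + 4 * madn(cv)
  flag <- use & !is.na(colvar) & colvar > thr
  idx <- which(flag, arr.ind = TRUE)
  data.frame(x = idx[, 1] - 1L, y = idx[, 2] - 1L)
}

#' Format the basic review quantities
#'
#' Renders the scalar QC record as ordered `key : value` text (the
#' "basic review") and optionally writes it to a file.
#'
#' @param qc Named list of scalar QC quantities (see [run_plan()]).
#' @param path Optional output text path.
#' @return Character vector of lines (invisibly the named list as
#'   attribute `record`).
#' @export
basic_review <- function(qc, path = NULL) {
  lines <- sprintf("%-28s : %s", names(qc),
                   vapply(qc, fmt_num, ""))
  if (!is.null(path)) writeLines(lines, path)
  structure(lines, record = qc)
}

#' Aggregate uvars files into a cross-subject review table
#'
#' One row per subject, one column per key (union across files; missing
#' keys are blank).  Unparseable files are listed, not fatal.  Criteria
#' of the form `"<key> <ge|le|gt|lt|eq> <value>"` flag outlier subjects.
#'
#' @param paths Character vector of uvars JSON paths.
#' @param criteria Optional character vector of outlier criteria.
#' @return List with `table` (data frame), `failed` (unparseable paths)
#'   and `outliers` (data frame of subject/criterion hits).
#' @export
review_table <- function(paths, criteria = NULL) {
  recs <- list(); failed <- character(0)
  for (p in paths) {
    r <- tryCatch(read_uvars(p), error = function(e) NULL)
    if (is.null(r)) failed <- c(failed, p) else recs[[p]] <- r
  }
  if (!length(recs)) return(list(table = data.frame(), failed = failed,
                                 outliers = data.frame()))
  keys <- unique(unlist(lapply(recs, names)))
  tab <- data.frame(file = names(recs), stringsAsFactors = FALSE)
  for (k in keys)
    tab[[k]] <- vapply(recs, function(r)
      if (is.null(r[[k]])) "" else as.character(r[[k]]), "")
  hits <- list()
  for (cr in criteria %||% character(0)) {
    parts <- strsplit(trimws(cr), "\\s+")[[1]]
    if (length(parts) != 3) stop2("criterion '%s' must be '<key> <op> <value>'", cr)
    key <- parts[1]; op <- parts[2]; val <- as.numeric(parts[3])
    f <- switch(op, ge = `>=`, le = `<=`, gt = `>`, lt = `<`, eq = `==`,
                stop2("unknown comparison '%s'", op))
    if (!key %in% keys) next
    x <- suppressWarnings(as.numeric(tab[[key]]))
    sel <- which(!is.na(x) & f(x, val))
    if (length(sel))
      hits[[cr]] <- data.frame(file = tab$file[sel], criterion = cr,
                               value = x[sel])
  }
  list(table = tab, failed = failed,
       outliers = if (length(hits)) do.call(rbind, hits)
                  else data.frame(file = character(0),
                                  criterion = character(0),
                                  value = numeric(0)))
}

# ---- static HTML report ---------------------------------------------------

# middle-axial-slice PNG of a map, optionally with transparent stat
# thresholding over an underlay: below-threshold overlay voxels get alpha
# proportional to |stat|/threshold, suprathreshold voxels are opaque.
write_slice_png <- function(path, under, over = NULL, threshold = NULL,
                            main = "") {
  z <- ceiling(dim(under)[3] / 2)
  u <- under[, , z]
  png(path, width = 480, height = 480)
  op <- par(mar = c(1, 1, 2, 1))
  image(u, col = gray(seq(0, 1, length.out = 128)), axes = FALSE,
        main = main, useRaster = TRUE)
  if (!is.null(over)) {
    o <- over[, , z]
    a <- if (is.null(threshold) || threshold <= 0) rep(1, length(o))
         else pmin(abs(as.vector(o)) / threshold, 1)
    a[!is.finite(a)] <- 0
    pos <- as.vector(o) >= 0
    ras <- matrix(grDevices::rgb(ifelse(pos, 1, 0), 0.1,
                                 ifelse(pos, 0, 1), alpha = a),
                  nrow(o), ncol(o))
    graphics::rasterImage(t(ras)[ncol(o):1, ], 0, 0, 1, 1,
                          interpolate = FALSE)
  }
  par(op); dev.off()
  path
}

censored_intervals <- function(keep) {
  r <- rle(!keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

write_motion_png <- function(path, censor) {
  n <- length(censor$enorm)
  png(path, width = 720, height = 320)
  op <- par(mar = c(4, 4, 2, 1))
  plot(seq_len(n), censor$enorm, type = "l", xlab = "volume",
       ylab = "Enorm (~mm)", main = "Motion (Enorm) and censoring")
  iv <- censored_intervals(censor$keep)
  if (nrow(iv))
    rect(iv$start - 0.5, par("usr")[3], iv$end + 0.5, par("usr")[4],
         col = grDevices::adjustcolor("red", 0.25), border = NA)
  thr <- censor$thresholds[["enorm"]]
  if (!is.na(thr)) abline(h = thr, col = "cyan3", lwd = 2)
  lines(seq_len(n), censor$enorm)
  par(op); dev.off()
  path
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the static QC HTML report
#'
#' Builds a single self-navigating HTML page with the standard sections
#' (`vorig` original data, `ve2a` EPI-anatomical alignment, `mot` motion
#' and censoring, `regr` regression results, `warns` warnings sorted by
#' severity, `radcor` radial correlation, `qsumm` the basic-review
#' summary).  Statistical overlays use transparent thresholding (alpha
#' grows linearly with |stat|/threshold below threshold, opaque above);
#' the motion plot shows the censor threshold line and shaded censored
#' intervals.  Missing maps render as an "absent" placeholder; the
#' rating widget is inert by design.
#'
#' @param qc QC record list (see [run_plan()]); recognised map entries:
#'   `epi_ref`, `anat`, `tsnr`, `radcor`, `stat`, `stat_threshold`,
#'   scalar list `scalars`, `censor` ([censor_series()]), `warnings`
#'   (data frame from [design_warnings()]).
#' @param out_dir Output directory (created if needed).
#' @return Path of the written `index.html`.
#' @export
render_apqc_html <- function(qc, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sections <- c(vorig = "Original data", ve2a = "EPI-anatomical alignment",
                mot = "Motion and censoring", regr = "Regression model",
                warns = "Warnings", radcor = "Radial correlation",
                qsumm = "Summary quantities")
  imgs <- list()
  if (!is.null(qc$epi_ref))
    imgs$vorig <- write_slice_png(file.path(out_dir, "vorig.png"),
                                  qc$epi_ref, main = "EPI reference")
  if (!is.null(qc$anat) && !is.null(qc$epi_ref))
    imgs$ve2a <- write_slice_png(file.path(out_dir, "ve2a.png"), qc$anat,
                                 main = "anatomical underlay")
  if (!is.null(qc$censor))
    imgs$mot <- write_motion_png(file.path(out_dir, "mot.png"), qc$censor)
  if (!is.null(qc$stat) && !is.null(qc$epi_ref))
    imgs$regr <- write_slice_png(file.path(out_dir, "regr.png"), qc$epi_ref,
                                 qc$stat, qc$stat_threshold %||% 2,
                                 main = "effect overlay (transparent thresholding)")
  if (!is.null(qc$radcor))
    imgs$radcor <- write_slice_png(file.path(out_dir, "radcor.png"),
                                   qc$radcor, main = "radial correlation")
  if (!is.null(qc$tsnr))
    imgs$qsumm_img <- write_slice_png(file.path(out_dir, "tsnr.png"),
                                      qc$tsnr, main = "TSNR")
  nav <- paste(sprintf("<a href='#%s'>%s</a>", names(sections), sections),
               collapse = " | ")
  body <- character(0)
  sev_rank <- c(severe = 1, medium = 2, mild = 3, none = 4)
  for (id in names(sections)) {
    body <- c(body, sprintf("<h2 id='%s'>%s</h2>", id, sections[id]))
    if (id == "warns") {
      w <- qc$warnings
      if (is.null(w) || !nrow(w)) {
        body <- c(body, "<p>no warnings</p>")
      } else {
        w <- w[order(sev_rank[w$level]), ]
        body <- c(body, "<ul>",
                  sprintf("<li><b>[%s]</b> %s: %s</li>", w$level,
                          html_escape(w$check), html_escape(w$message)),
                  "</ul>")
      }
      next
    }
    if (id == "qsumm") {
      sc <- qc$scalars
      if (!is.null(sc) && length(sc))
        body <- c(body, "<pre>",
                  html_escape(basic_review(sc)), "</pre>")
      if (!is.null(imgs$qsumm_img))
        body <- c(body, sprintf("<img src='%s'>", basename(imgs$qsumm_img)))
      next
    }
    if (!is.null(imgs[[id]]))
      body <- c(body, sprintf("<img src='%s'>", basename(imgs[[id]])))
    else
      body <- c(body, "<p><i>absent</i></p>")
  }
  rating <- paste0("<p>Rating: <button disabled>+</button>",
                   "<button disabled>-</button> (static report)</p>")
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>QC report</title></head><body>",
            sprintf("<h1>QC report (%s)</h1>", html_escape(epiproc_version())),
            sprintf("<p>%s</p>", nav), rating, body, "</body></html>")
  out <- file.path(out_dir, "index.html")
  writeLines(html, out)
  out
}
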