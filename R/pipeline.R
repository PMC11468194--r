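# The pipeline compiler: a hierarchical block+option specification is
# validated and resolved into an execution plan (every parameter filled,
# with a recorded user/default origin), rendered as a fully commented
# runnable R script that carries the generating command verbatim, and
# executed stage by stage.  The rendered script calls the very same
# stage executor the direct runner uses, so the two routes are identical
# by construction.

BLOCK_REGISTRY <- c("despike", "ricor", "tshift", "align", "tlrc",
                    "volreg", "combine", "blur", "mask", "scale",
                    "regress", "empty")
AUTO_BLOCKS <- c("setup", "tcat", "outcount", "QC_review")
DEFAULT_BLOCKS <- c("tshift", "volreg", "blur", "mask", "scale", "regress")
# canonical stage order (automatic blocks interleaved)
CANONICAL_ORDER <- c("setup", "tcat", "outcount", "despike", "ricor",
                     "tshift", "align", "tlrc", "volreg", "combine",
                     "blur", "mask", "scale", "empty", "regress",
                     "QC_review")

# option registry: name -> list(block, default)
option_registry <- function() list(
  tcat_remove_first_trs = list(block = "tcat", default = 0L),
  tshift_interp         = list(block = "tshift", default = "cubic"),
  tshift_align_to       = list(block = "tshift", default = 0),
  ricor_orders          = list(block = "ricor", default = 2L),
  ricor_rvt_shifts      = list(block = "ricor", default = c(0, 5, 10, 15, 20)),
  align_affine          = list(block = "align", default = NULL),
  align_check_flip      = list(block = "align", default = TRUE),
  tlrc_affine           = list(block = "tlrc", default = NULL),
  volreg_align_to       = list(block = "volreg", default = "MIN_OUTLIER"),
  volreg_warp_final_interp = list(block = "volreg", default = "trilinear"),
  volreg_warp_dxyz      = list(block = "volreg", default = NULL),
  combine_method        = list(block = "combine", default = "OC"),
  blur_size             = list(block = "blur", default = 4),
  mask_epi_anat         = list(block = "mask", default = FALSE),
  regress_polort        = list(block = "regress", default = "auto"),
  regress_basis         = list(block = "regress", default = "GAM"),
  regress_stim_types    = list(block = "regress", default = "time"),
  regress_censor_motion = list(block = "regress", default = 0.3),
  regress_censor_outliers = list(block = "regress", default = 0.05),
  regress_apply_mot_types = list(block = "regress", default = c("demean", "deriv")),
  regress_motion_per_run  = list(block = "regress", default = FALSE),
  regress_bandpass      = list(block = "regress", default = NULL),
  regress_reml          = list(block = "regress", default = "none"),
  regress_ROI_PC        = list(block = "regress", default = NULL))

#' Create a pipeline specification
#'
#' @param subject_id Subject identifier (used in output naming).
#' @param blocks Ordered character vector of processing blocks; `NULL`
#'   selects the default list `tshift, volreg, blur, mask, scale,
#'   regress`.
#' @param options Named list of block options (names as in the option
#'   registry, e.g. `blur_size`, `regress_censor_motion`).
#' @param inputs Named list: `epi` (a [volume4d()], [echo_set()], path or
#'   path vector), optional `anat` (3D [volume4d()] or path),
#'   `timing` ([timing_set()] or timing-file paths + `stim_labels`),
#'   `cardiac`/`resp` ([physio_trace()] or paths), `roi`
#'   ([roi_volume()]), `template` (declared template-space name).
#' @return Object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(subject_id, blocks = NULL, options = list(),
                          inputs = list()) {
  if (!nzchar(subject_id)) stop2("subject_id must be non-empty")
  blocks <- blocks %||% DEFAULT_BLOCKS
  structure(list(subject_id = subject_id, blocks = blocks,
                 options = options, inputs = inputs),
            class = "pipeline_spec")
}

spec_is_multiecho <- function(spec) {
  inherits(spec$inputs$epi, "echo_set") ||
    (!is.null(spec$inputs$echo_times) && length(spec$inputs$echo_times) > 1L)
}

#' Compile a specification into an execution plan
#'
#' Validates block names and options, fills every unset parameter with its
#' default (recording the origin of each value), inserts the automatic
#' stages (`setup`, `tcat`, `outcount`, `QC_review`) and the implicit
#' `combine` stage for multi-echo input, and orders everything
#' canonically (`despike`/`ricor` before `tshift`; `combine` directly
#' after `volreg`, before `blur`).  Every user option must be consumed by
#' exactly one present stage; an option addressed to an absent block is
#' an error, as are the explicitly unsupported `surf` and blip requests.
#'
#' @param spec A [pipeline_spec()].
#' @return Object of class `execution_plan`.
#' @export
assemble_plan <- function(spec) {
  blocks <- spec$blocks
  if (!length(blocks)) stop2("block list is empty")
  if (any(startsWith(blocks, "surf")))
    stop2("surface-based processing ('surf') is not supported")
  unknown <- setdiff(blocks, BLOCK_REGISTRY)
  if (length(unknown))
    stop2("unknown processing block(s): %s", paste(unknown, collapse = ", "))
  if (any(grepl("^blip", names(spec$options))) ||
      !is.null(spec$inputs$blip_forward) || !is.null(spec$inputs$blip_reverse))
    stop2("blip correction not supported")
  if (spec_is_multiecho(spec) && !"combine" %in% blocks)
    blocks <- c(blocks, "combine")   # implicit block for multi-echo input
  stages <- intersect(CANONICAL_ORDER, c(AUTO_BLOCKS, blocks))
  reg <- option_registry()
  bad <- setdiff(names(spec$options), names(reg))
  if (length(bad))
    stop2("unknown option(s): %s", paste(bad, collapse = ", "))
  consumed <- character(0)
  plan_stages <- list()
  for (b in stages) {
    opts <- reg[vapply(reg, function(o) o$block == b, TRUE)]
    params <- list(); origin <- character(0)
    for (nm in names(opts)) {
      pname <- sub(paste0("^", b, "_"), "", nm)
      if (nm %in% names(spec$options)) {
        params[[pname]] <- spec$options[[nm]]
        origin[pname] <- "user"
        consumed <- c(consumed, nm)
      } else {
        params[pname] <- list(opts[[nm]]$default)
        origin[pname] <- "default"
      }
    }
    plan_stages[[b]] <- list(block = b, params = params, origin = origin,
                             implicit = !(b %in% spec$blocks) &&
                               !(b %in% AUTO_BLOCKS))
  }
  orphans <- setdiff(names(spec$options), consumed)
  if (length(orphans)) {
    b <- reg[[orphans[1]]]$block
    stop2("option '%s' refers to block '%s' which is not in the stream",
          orphans[1], b)
  }
  structure(list(subject_id = spec$subject_id, stages = plan_stages,
                 inputs = spec$inputs, version = epiproc_version(),
                 multi_echo = spec_is_multiecho(spec)),
            class = "execution_plan")
}

#' @export
print.execution_plan <- function(x, ...) {
  cat(sprintf("<execution_plan '%s': %d stages>\n", x$subject_id,
              length(x$stages)))
  for (s in x$stages)
    cat(sprintf("  %-10s %s\n", s$block,
                if (s$implicit) "(implicit)" else ""))
  invisible(x)
}

stage_comment <- function(block) {
  switch(block,
         setup = "check inputs, create the results directory, copy data",
         tcat = "copy input datasets and remove unwanted initial volumes",
         outcount = "temporal outlier fractions and pre-steady-state check",
         despike = "truncate per-voxel temporal spikes",
         ricor = "project out slicewise cardiac/respiratory regressors",
         tshift = "align slices to a common temporal origin",
         align = "EPI to anatomical affine (user-supplied or identity)",
         tlrc = "anatomical to final-space affine (user-supplied)",
         volreg = "rigid-body motion estimation; single-step resampling through the concatenated transform",
         combine = "optimally combine echoes (T2*-weighted average)",
         blur = "spatial Gaussian smoothing",
         mask = "whole-brain mask estimation (never applied to the data)",
         scale = "scale each voxel's run mean to 100 (cap 200)",
         empty = "user placeholder (no-op)",
         regress = "design matrix, censoring and GLM as a single model",
         QC_review = "quality-control metrics, uvars dictionary and HTML report",
         block)
}

#' Render an execution plan as a commented runnable script
#'
#' Produces an R script that replays the plan stage by stage through
#' [execute_stage()], with one comment banner per stage, every resolved
#' parameter printed literally (defaults included, so the value actually
#' used is always visible), and the generating command embedded verbatim
#' in the header.  With a fixed `getOption("epiproc.timestamp")`,
#' rendering the same specification twice is byte-identical.
#'
#' @param plan An [assemble_plan()] result.
#' @param generating_command The command string that produced the plan.
#' @param out_dir Results directory the script will write to.
#' @return Object of class `proc_script` (list with `text`, `command`,
#'   `version`).
#' @export
render_script <- function(plan, generating_command = "",
                          out_dir = paste0(plan$subject_id, ".results")) {
  ts <- getOption("epiproc.timestamp",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  dep <- function(x) paste(deparse(x, control = c("keepNA", "niceNames")),
                           collapse = " ")
  lines <- c(
    "#!/usr/bin/env Rscript",
    sprintf("# proc script for subject %s", plan$subject_id),
    sprintf("# generated by   : %s", generating_command),
    sprintf("# version        : %s", plan$version),
    sprintf("# rendered       : %s", ts),
    "",
    "library(epiproc)",
    "",
    sprintf("state <- pipeline_init(subject_id = %s, inputs = %s, out_dir = %s)",
            dep(plan$subject_id), dep(plan$inputs), dep(out_dir)))
  for (s in plan$stages) {
    lines <- c(lines, "",
               sprintf("# %s", strrep("=", 66)),
               sprintf("# == block: %s%s -- %s", s$block,
                       if (s$implicit) " (implicit)" else "",
                       stage_comment(s$block)))
    if (length(s$params))
      lines <- c(lines, sprintf("# ==   %-24s = %s  [%s]", names(s$params),
                                vapply(s$params, dep, ""), s$origin))
    lines <- c(lines,
               sprintf("state <- execute_stage(state, %s, params = %s)",
                       dep(s$block), dep(s$params)))
  }
  lines <- c(lines, "",
             "manifest <- pipeline_finalize(state)")
  structure(list(text = paste0(paste(lines, collapse = "\n"), "\n"),
                 command = generating_command, version = plan$version),
            class = "proc_script")
}

#' @export
print.proc_script <- function(x, ...) { cat(x$text); invisible(x) }

#' Compare two pipeline specifications
#'
#' Both specifications are compiled (so every default is resolved) and the
#' per-stage parameter maps compared.  The report has three sections:
#' options only in `a`, only in `b`, and shared-but-different values.  An
#' option set explicitly in one spec and defaulted to the same value in
#' the other is not reported: equivalence is judged after resolution.
#'
#' @param a,b [pipeline_spec()] objects.
#' @return Object of class `spec_diff` with `only_a`, `only_b`,
#'   `different` (data frame) and `equivalent` (logical).
#' @export
compare_specs <- function(a, b) {
  flat <- function(spec) {
    pl <- assemble_plan(spec)
    out <- list()
    for (s in pl$stages)
      for (nm in names(s$params))
        out[[paste(s$block, nm, sep = ".")]] <- s$params[[nm]]
    out
  }
  fa <- flat(a); fb <- flat(b)
  only_a <- setdiff(names(fa), names(fb))
  only_b <- setdiff(names(fb), names(fa))
  shared <- intersect(names(fa), names(fb))
  differ <- shared[!vapply(shared, function(k)
    identical(fa[[k]], fb[[k]]), TRUE)]
  dd <- data.frame(option = differ,
                   a = vapply(fa[differ], function(x) paste(fmt_num(x), collapse = " "), ""),
                   b = vapply(fb[differ], function(x) paste(fmt_num(x), collapse = " "), ""),
                   row.names = NULL)
  structure(list(only_a = only_a, only_b = only_b, different = dd,
                 equivalent = !length(only_a) && !length(only_b) &&
                   !nrow(dd)),
            class = "spec_diff")
}

#' @export
print.spec_diff <- function(x, ...) {
  if (x$equivalent) { cat("specifications are equivalent\n"); return(invisible(x)) }
  if (length(x$only_a)) cat("only in a:", paste(x$only_a, collapse = ", "), "\n")
  if (length(x$only_b)) cat("only in b:", paste(x$only_b, collapse = ", "), "\n")
  if (nrow(x$different)) { cat("shared, different:\n"); print(x$different) }
  invisible(x)
}

# ---- execution ------------------------------------------------------------

load_epi_input <- function(epi, echo_times = NULL) {
  if (inherits(epi, "echo_set") || inherits(epi, "volume4d")) return(epi)
  if (is.character(epi)) {
    vols <- lapply(epi, read_nifti)
    if (!is.null(echo_times) && length(echo_times) > 1L)
      return(echo_set(vols, echo_times))
    if (length(vols) == 1L) return(vols[[1]])
    # multiple runs: concatenate along time, keeping run boundaries
    runs <- vapply(vols, n_volumes, 1L)
    dat <- array(0, c(vols[[1]]$grid$dims, sum(runs)))
    at <- 0L
    for (v in vols) { dat[, , , at + seq_len(n_volumes(v))] <- v$data
                      at <- at + n_volumes(v) }
    return(volume4d(dat, grid = vols[[1]]$grid, tr = vols[[1]]$tr,
                    slice_times = vols[[1]]$slice_times, runs = runs))
  }
  stop2("unsupported EPI input")
}

#' Initialise pipeline execution state
#'
#' Creates the `<subject>.results` directory (refusing to write into a
#' non-empty one unless `overwrite`), loads the inputs, opens the terminal
#' log, and returns the state object threaded through [execute_stage()].
#'
#' @param subject_id Subject identifier.
#' @param inputs As in [pipeline_spec()].
#' @param out_dir Results directory path.
#' @param overwrite Allow writing into an existing non-empty directory?
#' @return Pipeline state (a list; treat as opaque).
#' @export
pipeline_init <- function(subject_id, inputs, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop2("output directory %s exists and is not empty (use overwrite)", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "output.log")
  logf <- function(msg) cat(sprintf("[%s] %s\n",
                                    format(Sys.time(), "%H:%M:%S"), msg),
                            file = log_path, append = TRUE)
  logf(sprintf("pipeline start: %s (%s)", subject_id, epiproc_version()))
  epi <- load_epi_input(inputs$epi, inputs$echo_times)
  anat <- inputs$anat
  if (is.character(anat)) anat <- read_nifti(anat)
  timing <- inputs$timing
  if (is.character(timing))
    timing <- read_stim_timing(timing, inputs$stim_labels %||% basename(timing))
  tr_of <- function(x) if (inherits(x, "echo_set")) x$echoes[[1]]$tr else x$tr
  manifest <- list()
  # copy original file inputs into the results directory
  for (nm in names(inputs)) {
    p <- inputs[[nm]]
    if (is.character(p) && all(file.exists(p))) {
      dest <- file.path(out_dir, basename(p))
      file.copy(p, dest, overwrite = TRUE)
      manifest[[paste0("input_", nm)]] <- dest
    }
  }
  cardiac <- inputs$cardiac
  if (is.character(cardiac)) cardiac <- read_physio_trace(cardiac)
  resp <- inputs$resp
  if (is.character(resp)) resp <- read_physio_trace(resp)
  list(subj = subject_id, dir = out_dir, log = logf,
       epi = epi, anat = anat, timing = timing,
       cardiac = cardiac, resp = resp, roi = inputs$roi,
       template = inputs$template,
       pb = -1L, manifest = manifest, qc = list(),
       epi2anat = diag(4), anat2final = diag(4),
       mp = NULL, censor = NULL, outlier_frac = NULL, presteady = 0L,
       mask = NULL, physio = NULL, physio_df = 0L, glm = NULL,
       warnings = NULL, removed_trs = 0L)
}

state_vol <- function(state) {
  if (inherits(state$epi, "echo_set")) state$epi$echoes[[1]] else state$epi
}

state_map_epi <- function(state, f) {
  if (inherits(state$epi, "echo_set")) {
    state$epi$echoes <- lapply(state$epi$echoes, f)
  } else state$epi <- f(state$epi)
  state
}

write_pb <- function(state, block) {
  state$pb <- state$pb + 1L
  stem <- sprintf("pb%02d.%s.%s", state$pb, state$subj, block)
  if (inherits(state$epi, "echo_set")) {
    for (e in seq_along(state$epi$echoes)) {
      p <- file.path(state$dir, sprintf("%s.e%02d.nii.gz", stem, e))
      write_nifti(state$epi$echoes[[e]], p)
      state$manifest[[sprintf("%s.e%02d", stem, e)]] <- p
    }
  } else {
    p <- file.path(state$dir, paste0(stem, ".nii.gz"))
    write_nifti(state$epi, p)
    state$manifest[[stem]] <- p
  }
  state
}

# quick automask of the current EPI (first echo), for internal statistics
interim_mask <- function(state) {
  state$mask %||% compute_epi_automask(state_vol(state))
}

#' Execute one pipeline stage
#'
#' The single stage executor behind both [run_plan()] and the rendered
#' proc script.  See [assemble_plan()] for the stage vocabulary.
#'
#' @param state Pipeline state from [pipeline_init()].
#' @param block Stage name.
#' @param params Resolved stage parameters.
#' @return Updated state.
#' @export
execute_stage <- function(state, block, params = list()) {
  state$log(sprintf("stage %s start", block))
  state <- switch(
    block,
    setup = state,
    tcat = {
      n <- as.integer(params$remove_first_trs %||% 0L)
      state$removed_trs <- n
      state <- state_map_epi(state, function(v) remove_initial_volumes(v, n))
      write_pb(state, "tcat")
    },
    outcount = {
      m <- interim_mask(state)
      state$outlier_frac <- temporal_outlier_fraction(state_vol(state), m)
      state$presteady <- detect_pre_steady_state(state_vol(state), m)
      write_column_file(cbind(state$outlier_frac),
                        file.path(state$dir, "outcount.1D"))
      state$manifest$outcount <- file.path(state$dir, "outcount.1D")
      state
    },
    despike = {
      state <- state_map_epi(state, despike_volume)
      write_pb(state, "despike")
    },
    ricor = {
      if (is.null(state$cardiac) && is.null(state$resp))
        stop2("ricor block requested but no physiological traces given")
      pr <- build_physio_regressors(state$cardiac, state$resp,
                                    state_vol(state),
                                    orders = params$orders %||% 2,
                                    shifts_s = params$rvt_shifts %||%
                                      c(0, 5, 10, 15, 20))
      state$physio <- pr
      state$physio_df <- length(pr$labels) + ncol(pr$volumetric)
      state <- state_map_epi(state, function(v) project_physio(v, pr))
      write_pb(state, "ricor")
    },
    tshift = {
      state <- state_map_epi(state, function(v)
        slice_time_correct(v, method = params$interp %||% "cubic",
                           align_to = params$align_to %||% 0))
      write_pb(state, "tshift")
    },
    align = {
      if (!is.null(params$affine))
        state$epi2anat <- as_affine(params$affine)
      if (!is.null(state$anat) && isTRUE(params$check_flip %||% TRUE) &&
          grids_equal(state$anat$grid, state_vol(state)$grid)) {
        ref <- state_vol(state)$data[, , , 1]
        fc <- left_right_flip_check(ref, state$anat$data[, , , 1],
                                    state_vol(state)$grid)
        state$qc$flip_verdict <- fc$verdict
        state$qc$lpc_cost <- fc$cost_as_is
      }
      state
    },
    tlrc = {
      if (!is.null(params$affine))
        state$anat2final <- as_affine(params$affine)
      state
    },
    volreg = {
      v <- state_vol(state)
      ref <- params$align_to %||% "MIN_OUTLIER"
      ref_index <- if (identical(ref, "MIN_OUTLIER")) {
        of <- state$outlier_frac %||%
          temporal_outlier_fraction(v, interim_mask(state))
        which.min(of)
      } else as.integer(ref)
      state$mp <- estimate_rigid_motion(v, ref_index)
      out_grid <- if (is.null(params$warp_dxyz)) NULL
                  else if (identical(params$warp_dxyz, "auto"))
                    default_output_grid(v$grid)
                  else {
                    g <- v$grid
                    make_grid(ceiling(g$dims * g$voxel_size / params$warp_dxyz),
                              rep(params$warp_dxyz, 3))
                  }
      kern <- params$warp_final_interp %||% "trilinear"
      state <- state_map_epi(state, function(x)
        apply_concatenated_transform(x, state$mp, state$epi2anat,
                                     state$anat2final, out_grid, kern))
      mp_path <- file.path(state$dir, "dfile_rall.1D")
      write_column_file(unclass(state$mp), mp_path,
                        comment = "roll pitch yaw dS dL dP")
      state$manifest$motion <- mp_path
      write_pb(state, "volreg")
    },
    combine = {
      if (!inherits(state$epi, "echo_set"))
        stop2("combine block requires multi-echo input")
      method <- params$method %||% "OC"
      if (!method %in% c("OC", "mean"))
        stop2("unsupported combine method '%s' (only OC and mean)", method)
      if (method == "OC") {
        oc <- fit_t2star_and_combine(state$epi)
        state$qc$t2star_median <- median(oc$weights$t2star, na.rm = TRUE)
        state$epi <- oc$combined
      } else {
        acc <- state$epi$echoes[[1]]$data * 0
        for (e in state$epi$echoes) acc <- acc + e$data
        state$epi <- vol_with(state$epi$echoes[[1]],
                              acc / length(state$epi$echoes))
      }
      write_pb(state, "combine")
    },
    blur = {
      state <- state_map_epi(state, function(v)
        gaussian_blur(v, params$size %||% 4))
      write_pb(state, "blur")
    },
    mask = {
      anat_mask <- NULL
      if (isTRUE(params$epi_anat) && !is.null(state$anat) &&
          grids_equal(state$anat$grid, state_vol(state)$grid))
        anat_mask <- state$anat$data[, , , 1] > 0
      state$mask <- compute_epi_automask(state_vol(state), anat_mask)
      mk <- volume4d(array(as.numeric(state$mask), dim(state$mask)),
                     grid = state_vol(state)$grid, tr = state_vol(state)$tr)
      p <- file.path(state$dir, sprintf("mask_epi.%s.nii.gz", state$subj))
      write_nifti(mk, p)
      state$manifest$mask <- p
      state
    },
    scale = {
      state <- state_map_epi(state, scale_percent)
      write_pb(state, "scale")
    },
    empty = state,
    regress = execute_regress(state, params),
    QC_review = execute_qc_review(state),
    stop2("unknown stage '%s'", block))
  state$log(sprintf("stage %s done", block))
  state
}

as_affine <- function(x) {
  if (is.character(x)) x <- as.matrix(read_column_file(x))
  x <- as.matrix(x)
  if (!identical(dim(x), c(4L, 4L))) stop2("affine must be 4x4")
  x
}

# project slicewise + volumetric physio regressors (plus a constant) out
# of the data, slice by slice
project_physio <- function(vol, pr) {
  d <- dim(vol$data)
  Y <- vol_as_tv(vol)
  vox_slice <- rep(seq_len(d[3]), each = d[1] * d[2])
  for (z in seq_len(d[3])) {
    X <- cbind(1, pr$volumetric, pr$slicewise[, , z])
    vi <- which(vox_slice == z)
    B <- qr.coef(qr(X), Y[, vi, drop = FALSE])
    B[is.na(B)] <- 0
    # keep the mean: add back the constant fit
    Y[, vi] <- Y[, vi, drop = FALSE] - X[, -1, drop = FALSE] %*%
      B[-1, , drop = FALSE]
  }
  tv_as_vol(Y, vol)
}

execute_regress <- function(state, params) {
  vol <- state_vol(state)
  runs <- vol$runs
  parts <- list(baseline = baseline_regressors(runs, vol$tr,
                                               params$polort %||% "auto"))
  enorm <- if (!is.null(state$mp)) enorm_series(state$mp, runs)
           else rep(0, n_volumes(vol))
  if (!is.null(state$mp))
    parts$motion <- motion_regressors(state$mp,
                                      params$apply_mot_types %||%
                                        c("demean", "deriv"),
                                      per_run = isTRUE(params$motion_per_run),
                                      run_lengths = runs)
  if (!is.null(params$bandpass))
    parts$bandpass <- bandpass_regressors(runs, vol$tr,
                                          params$bandpass[1],
                                          params$bandpass[2])
  if (!is.null(params$ROI_PC) && !is.null(state$roi))
    parts$roi_pc <- roi_pc_regressors(vol, state$roi,
                                      params$ROI_PC$label,
                                      params$ROI_PC$k %||% 3,
                                      per_run = isTRUE(params$motion_per_run))
  if (!is.null(state$timing)) {
    spec_b <- basis_spec(params$basis %||% "GAM")
    stypes <- params$stim_types %||% "time"
    labs <- names(state$timing$classes)
    if (length(stypes) == 1L) stypes <- rep(stypes, length(labs))
    for (i in seq_along(labs))
      parts[[paste0("stim:", labs[i])]] <-
        event_regressors(state$timing, labs[i], spec_b, stypes[i],
                         runs, vol$tr)
  }
  of <- state$outlier_frac %||% rep(0, n_volumes(vol))
  if (length(of) != n_volumes(vol)) of <- rep(0, n_volumes(vol))
  censor <- build_censor(enorm, of,
                         params$censor_motion %||% 0.3,
                         params$censor_outliers %||% 0.05)
  X <- assemble_design(parts, censor, runs, vol$tr)
  state$glm <- fit_glm(vol, X,
                       whiten = if (identical(params$reml, "ar1")) "ar1"
                                else "none",
                       mask = state$mask)
  state$censor <- censor
  state$ledger <- compute_df_ledger(X)
  if (state$physio_df > 0) {
    # regressors already projected in the ricor block still cost DFs
    state$ledger$used <- c(state$ledger$used, ricor = state$physio_df)
    state$ledger$df_remaining <- state$ledger$df_remaining - state$physio_df
  }
  state$warnings <- design_warnings(X, state$timing,
                                    presteady_count =
                                      max(0L, state$presteady))
  # outputs
  dm_path <- file.path(state$dir, "X.xmat.1D")
  write_column_file(X$X, dm_path,
                    comment = c(paste("labels:", paste(X$labels[seq_len(ncol(X$X))], collapse = " ")),
                                paste("categories:", paste(X$category[seq_len(ncol(X$X))], collapse = " "))))
  cen_path <- file.path(state$dir, sprintf("censor_%s.1D", state$subj))
  write_column_file(cbind(as.numeric(censor$keep)), cen_path)
  errts_path <- file.path(state$dir, sprintf("errts.%s.nii.gz", state$subj))
  write_nifti(state$glm$errts, errts_path)
  state$manifest$design <- dm_path
  state$manifest$censor <- cen_path
  state$manifest$errts <- errts_path
  # full-model F as the stats volume
  stats <- volume4d(array(state$glm$fstat, vol$grid$dims), grid = vol$grid,
                    tr = vol$tr, units = "statistic")
  st_path <- file.path(state$dir, sprintf("stats.%s.nii.gz", state$subj))
  write_nifti(stats, st_path)
  state$manifest$stats <- st_path
  state
}

execute_qc_review <- function(state) {
  vol <- state_vol(state)
  mask <- interim_mask(state)
  tsnr <- tsnr_map(vol, residuals = if (!is.null(state$glm))
    state$glm$errts else NULL, mask = mask)
  radcor <- radial_correlation(vol)
  gc <- gcor(vol, mask)
  corr_brain <- average_roi_correlation_map(vol, mask)
  seeds <- default_seed_locations(vol$grid, state$template)
  seed_maps <- lapply(seeds, function(s)
    seed_correlation_map(vol, s, state$censor))
  enorm <- if (!is.null(state$censor)) state$censor$enorm
           else rep(0, n_volumes(vol))
  n_cens <- if (!is.null(state$censor)) sum(!state$censor$keep) else 0L
  scalars <- list(
    subject_id = state$subj,
    tr = vol$tr,
    n_volumes = n_volumes(vol),
    n_runs = length(vol$runs),
    removed_first_trs = state$removed_trs,
    pre_steady_state = state$presteady,
    n_censored = n_cens,
    censor_frac = round(n_cens / n_volumes(vol), 4),
    max_enorm = round(max(enorm), 4),
    tsnr_mean = round(attr(tsnr, "mean_in_mask") %||%
                        mean(tsnr$data[as.vector(mask)]), 3),
    gcor = round(gc, 5),
    df_remaining = if (!is.null(state$ledger)) state$ledger$df_remaining
                   else NA_integer_,
    flip_verdict = state$qc$flip_verdict %||% "not_checked",
    version = epiproc_version())
  qcdir <- file.path(state$dir, sprintf("QC_%s", state$subj))
  dir.create(qcdir, showWarnings = FALSE)
  for (nm in names(seed_maps))
    write_nifti(seed_maps[[nm]],
                file.path(qcdir, sprintf("seed_%s.nii.gz", nm)))
  write_nifti(tsnr, file.path(qcdir, "tsnr.nii.gz"))
  write_nifti(radcor, file.path(qcdir, "radcor.nii.gz"))
  write_nifti(corr_brain, file.path(qcdir, "corr_brain.nii.gz"))
  qc <- list(epi_ref = vol$data[, , , 1],
             anat = if (!is.null(state$anat)) state$anat$data[, , , 1],
             tsnr = tsnr$data[, , , 1], radcor = radcor$data[, , , 1],
             stat = if (!is.null(state$glm))
               array(state$glm$fstat, vol$grid$dims),
             stat_threshold = 10,
             censor = state$censor, warnings = state$warnings,
             scalars = scalars)
  html <- render_apqc_html(qc, qcdir)
  uv_path <- file.path(state$dir, sprintf("out.ss_review_uvars.%s.json",
                                          state$subj))
  write_uvars(scalars, uv_path)
  basic_review(scalars, file.path(state$dir, "out.ss_review_basic.txt"))
  state$manifest$uvars <- uv_path
  state$manifest$qc_html <- html
  state$manifest$basic_review <- file.path(state$dir,
                                           "out.ss_review_basic.txt")
  state$qc$scalars <- scalars
  state
}

#' Compile and execute a plan
#'
#' Runs every stage of the plan into `<subject>.results`, producing the
#' per-stage `pb<k>` datasets, motion/censor/design column files, stats
#' and errts volumes, the uvars dictionary, the basic-review text and the
#' QC HTML directory.  A stage failure aborts with the stage name; prior
#' outputs are left intact.
#'
#' @param plan An [assemble_plan()] result (or a [pipeline_spec()], which
#'   is compiled first).
#' @param out_dir Results directory (default `<subject>.results`).
#' @param overwrite Allow writing into an existing non-empty directory?
#' @return The results manifest: named list of output paths plus
#'   `scalars`.
#' @export
run_plan <- function(plan, out_dir = NULL, overwrite = FALSE) {
  if (inherits(plan, "pipeline_spec")) plan <- assemble_plan(plan)
  out_dir <- out_dir %||% paste0(plan$subject_id, ".results")
  state <- pipeline_init(plan$subject_id, plan$inputs, out_dir, overwrite)
  for (s in plan$stages) {
    state <- tryCatch(
      execute_stage(state, s$block, s$params),
      error = function(e)
        stop2("stage '%s' failed: %s", s$block, conditionMessage(e)))
  }
  pipeline_finalize(state)
}

#' Finalise a pipeline run
#'
#' Writes the run manifest JSON and returns it.
#'
#' @param state Pipeline state after the last stage.
#' @return Named list of output paths plus `scalars`.
#' @export
pipeline_finalize <- function(state) {
  man <- state$manifest
  man_path <- file.path(state$dir, "manifest.json")
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, pretty = TRUE)
  state$log("pipeline complete")
  c(man, list(manifest = man_path, scalars = state$qc$scalars))
}

# ---- spec files and examples ---------------------------------------------

#' Read a pipeline specification file
#'
#' Flat `key value...` lines; `#` comments; repeated keys accumulate into
#' vectors (e.g. several `epi` lines for multiple runs).  Recognised input
#' keys: `subject_id`, `blocks`, `epi`, `anat`, `echo_times`,
#' `stim_times`, `stim_labels`, `cardiac`, `resp`, `template`; every
#' other key must be a registered option.
#'
#' @param path Spec file path.
#' @return A [pipeline_spec()].
#' @export
read_pipeline_spec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- list()
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- toks[1]; val <- toks[-1]
    num <- suppressWarnings(as.numeric(val))
    if (length(val) && !anyNA(num)) val <- num
    kv[[key]] <- c(kv[[key]], val)
  }
  input_keys <- c("epi", "anat", "echo_times", "stim_times", "stim_labels",
                  "cardiac", "resp", "template")
  inputs <- kv[intersect(names(kv), input_keys)]
  if (!is.null(inputs$stim_times)) {
    inputs$timing <- inputs$stim_times
    inputs$stim_times <- NULL
  }
  opts <- kv[setdiff(names(kv), c(input_keys, "subject_id", "blocks"))]
  bool_like <- function(x) if (is.character(x) && length(x) == 1 &&
                               x %in% c("yes", "no", "TRUE", "FALSE"))
    x %in% c("yes", "TRUE") else x
  opts <- lapply(opts, bool_like)
  pipeline_spec(subject_id = kv$subject_id %||% "subj",
                blocks = kv$blocks, options = opts, inputs = inputs)
}

#' Show a packaged example specification
#'
#' @param name One of `task_basic`, `rest_bandpass`, `multi_echo`.
#' @return The spec file text, invisibly; it is also printed.
#' @export
show_example <- function(name = c("task_basic", "rest_bandpass",
                                  "multi_echo")) {
  name <- match.arg(name)
  path <- system.file("examples", paste0(name, ".cfg"), package = "epiproc")
  if (!nzchar(path)) stop2("example '%s' not found", name)
  txt <- readLines(path)
  cat(txt, sep = "\n")
  invisible(txt)
}
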