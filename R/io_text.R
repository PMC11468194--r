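# Plain-text interchange: whitespace-delimited column files ('#' comments)
# for motion/censor/regressor series, AFNI-style stimulus timing files,
# BIDS-style events tables, and the JSON uvars dictionary.

#' Read a whitespace-delimited numeric column file
#'
#' Rows are time points and columns are series.  Lines starting with `#`
#' are comments; blank lines are skipped.
#'
#' @param path File path.
#' @return Numeric matrix (time x series).
#' @export
read_column_file <- function(path) {
  if (!file.exists(path)) stop2("column file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  if (!length(toks)) stop2("%s: no data rows", path)
  nc <- length(toks[[1]])
  for (i in seq_along(toks)) {
    if (length(toks[[i]]) != nc)
      stop2("%s: ragged row at line %d (%d fields, expected %d)",
            path, rows[i], length(toks[[i]]), nc)
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop2("%s: non-numeric token '%s' at line %d",
          path, unlist(toks)[bad], rows[ceiling(bad / nc)])
  }
  matrix(vals, ncol = nc, byrow = TRUE)
}

#' Write a numeric matrix as a column file
#'
#' @param mat Numeric matrix or vector.
#' @param path Output path.
#' @param comment Optional comment lines (written with `#` prefixes, after
#'   an automatic provenance line).
#' @return Invisibly, `path`.
#' @export
write_column_file <- function(mat, path, comment = character(0)) {
  mat <- as.matrix(mat)
  hdr <- paste0("# ", c(provenance_note("write_column_file"), comment))
  body <- apply(mat, 1, function(r) paste(format(r, digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- AFNI-style stimulus timing ------------------------------------------

parse_timing_token <- function(tok, path, row) {
  # grammar: onset[*amp[*amp...]][:dur]
  m <- regmatches(tok, regexec(
    "^(-?[0-9.eE+-]+)((\\*[0-9.eE+-]+)*)(:([0-9.eE+-]+))?$", tok))[[1]]
  if (!length(m))
    stop2("%s row %d: malformed timing token '%s'", path, row, tok)
  onset <- suppressWarnings(as.numeric(m[2]))
  dur <- if (nzchar(m[6])) suppressWarnings(as.numeric(m[6])) else NA_real_
  mods <- if (nzchar(m[3]))
    suppressWarnings(as.numeric(strsplit(sub("^\\*", "", m[3]), "\\*")[[1]]))
  else numeric(0)
  if (is.na(onset) || (nzchar(m[6]) && is.na(dur)) || anyNA(mods))
    stop2("%s row %d: malformed timing token '%s'", path, row, tok)
  if (onset < 0)
    stop2("%s row %d: negative onset in token '%s'", path, row, tok)
  if (!is.na(dur) && dur < 0)
    stop2("%s row %d: negative duration in token '%s'", path, row, tok)
  list(onset = onset, duration = dur, modulators = mods)
}

empty_run <- function() list(onset = numeric(0), duration = numeric(0),
                             modulators = matrix(0, 0, 0))

#' Read AFNI-style stimulus timing files
#'
#' One file per stimulus class, one row per run.  Tokens are `onset`,
#' `onset:dur`, `onset*amp` or `onset*amp1*amp2:dur` (married duration /
#' amplitude values); a row of `*` or `-1` marks an empty run.  Mixing
#' different modulator counts within a class is rejected rather than
#' guessed at.
#'
#' @param paths Character vector of file paths, one per class.
#' @param labels Class labels, same length as `paths`.
#' @return A [timing_set()].
#' @export
read_stim_timing <- function(paths, labels = basename(paths)) {
  if (length(paths) != length(labels)) stop2("one label per timing file")
  classes <- list()
  for (i in seq_along(paths)) {
    path <- paths[i]
    if (!file.exists(path)) stop2("timing file does not exist: %s", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    runs <- list()
    for (r in seq_along(lines)) {
      toks <- strsplit(trimws(lines[r]), "\\s+")[[1]]
      if (identical(toks, "*") || identical(toks, "-1")) {
        runs[[r]] <- empty_run()
        next
      }
      ev <- lapply(seq_along(toks), function(j)
        parse_timing_token(toks[j], path, r))
      onset <- vapply(ev, `[[`, 0, "onset")
      if (is.unsorted(onset))
        stop2("%s row %d: onsets must be non-decreasing", path, r)
      nmod <- vapply(ev, function(e) length(e$modulators), 1L)
      if (length(unique(nmod)) > 1L)
        stop2("%s row %d: mixed modulator counts across events", path, r)
      runs[[r]] <- list(
        onset = onset,
        duration = vapply(ev, `[[`, 0, "duration"),
        modulators = if (nmod[1] > 0)
          do.call(rbind, lapply(ev, `[[`, "modulators"))
        else matrix(0, length(ev), 0))
    }
    classes[[labels[i]]] <- runs
  }
  timing_set(classes)
}

#' Write a timing set as AFNI-style timing files
#'
#' Inverse of [read_stim_timing()]: emits the same married-token grammar.
#'
#' @param ts A [timing_set()].
#' @param dir Output directory.
#' @param prefix File name prefix; files are `<prefix><label>.txt`.
#' @return Named character vector of written paths.
#' @export
write_stim_timing <- function(ts, dir, prefix = "times_") {
  paths <- character(0)
  for (lab in names(ts$classes)) {
    rows <- vapply(ts$classes[[lab]], function(ev) {
      if (!length(ev$onset)) return("*")
      tok <- fmt_num(ev$onset)
      if (ncol(ev$modulators) > 0)
        tok <- paste0(tok, apply(ev$modulators, 1, function(m)
          paste0("*", fmt_num(m), collapse = "")))
      has_dur <- !is.na(ev$duration)
      tok[has_dur] <- paste0(tok[has_dur], ":", fmt_num(ev$duration[has_dur]))
      paste(tok, collapse = " ")
    }, "")
    p <- file.path(dir, paste0(prefix, lab, ".txt"))
    writeLines(rows, p)
    paths[lab] <- p
  }
  paths
}

#' Read a BIDS-style events table
#'
#' Expects a TSV with `onset` and `duration` columns; one stimulus class is
#' created per distinct value of `class_column`.  An optional `run` column
#' assigns events to runs; a numeric column named by `modulator_column`
#' (when present) becomes a married amplitude modulator.
#'
#' @param path TSV path.
#' @param class_column Column naming the event class (default
#'   `"trial_type"`).
#' @param n_runs Total number of runs (so trailing empty runs survive).
#' @param modulator_column Optional modulator column name.
#' @return A [timing_set()].
#' @export
read_events_tsv <- function(path, class_column = "trial_type",
                            n_runs = NULL, modulator_column = NULL) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (col in c("onset", "duration", class_column))
    if (!col %in% names(tab)) stop2("%s: missing required column '%s'", path, col)
  run <- if ("run" %in% names(tab)) as.integer(tab$run) else rep(1L, nrow(tab))
  n_runs <- n_runs %||% max(run)
  classes <- list()
  for (lab in unique(tab[[class_column]])) {
    runs <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      sel <- which(tab[[class_column]] == lab & run == r)
      sel <- sel[order(tab$onset[sel])]
      if (!length(sel)) { runs[[r]] <- empty_run(); next }
      runs[[r]] <- list(
        onset = tab$onset[sel],
        duration = tab$duration[sel],
        modulators = if (!is.null(modulator_column))
          matrix(tab[[modulator_column]][sel], ncol = 1)
        else matrix(0, length(sel), 0))
    }
    classes[[as.character(lab)]] <- runs
  }
  timing_set(classes)
}

#' Write a timing set as a BIDS-style events table
#'
#' Inverse of [read_events_tsv()]: one row per event with `onset`,
#' `duration` (0 where absent), `trial_type`, `run`, and a `modulator`
#' column when any class carries married amplitudes.
#'
#' @param ts A [timing_set()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_events_tsv <- function(ts, path) {
  rows <- list()
  any_mod <- any(vapply(ts$classes, function(cl)
    any(vapply(cl, function(ev) ncol(ev$modulators) > 0, TRUE)), TRUE))
  for (lab in names(ts$classes)) {
    for (r in seq_along(ts$classes[[lab]])) {
      ev <- ts$classes[[lab]][[r]]
      if (!length(ev$onset)) next
      row <- data.frame(onset = ev$onset,
                        duration = ifelse(is.na(ev$duration), 0, ev$duration),
                        trial_type = lab, run = r)
      if (any_mod)
        row$modulator <- if (ncol(ev$modulators)) ev$modulators[, 1] else 1
      rows[[length(rows) + 1]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$run, tab$onset), ]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- uvars JSON -----------------------------------------------------------

#' Write the uvars dictionary
#'
#' The uvars file is the machine-readable reference dictionary of key
#' quantities and dataset paths produced by a pipeline run.  It is a flat
#' JSON object with sorted keys; nested values are rejected by contract.
#'
#' @param record Named list of scalar values, strings or file paths.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_uvars <- function(record, path) {
  if (is.null(names(record)) || any(names(record) == ""))
    stop2("uvars record must be a fully named list")
  for (k in names(record)) {
    v <- record[[k]]
    if (is.list(v) || length(v) != 1L)
      stop2("uvars value '%s' is not a scalar (flat dictionary contract)", k)
  }
  record <- record[order(names(record))]
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_uvars
#' @export
read_uvars <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
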