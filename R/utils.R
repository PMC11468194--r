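# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Robust spread: normalized median absolute deviation (consistent for
# a Gaussian), computed without stats::mad's centring options overhead.
madn <- function(x) 1.4826 * median(abs(x - median(x)))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

stop2 <- function(...) stop(sprintf(...), call. = FALSE)
warn2 <- function(...) warning(sprintf(...), call. = FALSE)

# Accumulating history note attached to every written artifact.  A fixed
# timestamp can be injected (option "epiproc.timestamp") so that rendering
# the same specification twice is byte-identical.
provenance_note <- function(action) {
  ts <- getOption("epiproc.timestamp",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  sprintf("[%s] %s :: %s", ts, epiproc_version(), action)
}

# run lengths -> integer run id per volume
run_ids <- function(run_lengths) rep.int(seq_along(run_lengths), run_lengths)

# Split 1:n into per-run index lists
run_index <- function(run_lengths) {
  split(seq_len(sum(run_lengths)), run_ids(run_lengths))
}

fmt_num <- function(x) {
  if (is.numeric(x)) format(x, digits = 10, trim = TRUE) else as.character(x)
}
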