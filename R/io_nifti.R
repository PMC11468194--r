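# NIFTI-1 reading and writing (via RNifti).  Only NIFTI-1 is supported;
# the units tag and an accumulating provenance note travel in the header
# description field (80 bytes, so the note is truncated from the left).

units_from_descrip <- function(descrip) {
  m <- regmatches(descrip, regexpr("units=[a-z]+", descrip))
  if (length(m) && nchar(m)) sub("units=", "", m) else "raw"
}

slice_times_from_header <- function(hdr, nz, tr) {
  code <- hdr$slice_code %||% 0L
  dur <- hdr$slice_duration %||% 0
  if (code <= 0L || dur <= 0 || nz < 2L) return(numeric(0))
  ord <- switch(as.character(code),
                "1" = seq_len(nz),                      # seq ascending
                "2" = rev(seq_len(nz)),                 # seq descending
                "3" = c(seq(1, nz, 2), seq(2, nz, 2)),  # alt ascending
                "4" = rev(c(seq(1, nz, 2), seq(2, nz, 2))),
                NULL)
  if (is.null(ord)) return(numeric(0))
  st <- numeric(nz)
  st[ord] <- (seq_len(nz) - 1) * dur
  if (any(st >= tr)) return(numeric(0))
  st
}

#' Read a NIFTI-1 volume
#'
#' Reads a 3D or 4D NIFTI-1 file into a [volume4d()].  3D inputs become a
#' single-volume series with no slice timing.  Header slope/intercept
#' scaling is applied by the reader.  A zero (or missing) header TR on 4D
#' data is replaced by 1.0 s with a warning, so that a malformed header
#' surfaces without stopping the pipeline.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volume4d()].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop2("NIFTI file does not exist: %s", path)
  ver <- tryCatch(RNifti::niftiVersion(path), error = function(e) -1L)
  if (is.na(ver[1]) || ver[1] < 1L)
    stop2("%s is not a NIFTI-1 file (magic check failed)", path)
  # header is read from the path so that raw (unsanitised) fields like a
  # zero TR remain observable
  hdr <- RNifti::niftiHeader(path)
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))  # drop reader bookkeeping attrs
  nd <- length(dim(data))
  if (nd == 2L) dim(data) <- c(dim(data), 1L, 1L)
  if (nd == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop2("%s: unsupported dimensionality (%dD)", path, nd)
  d <- dim(data)
  tr <- hdr$pixdim[5]
  if (d[4] > 1L && (is.na(tr) || tr <= 0)) {
    warn2("%s: 4D data with zero/absent header TR; assuming TR = 1.0 s", path)
    tr <- 1.0
  }
  if (d[4] == 1L && (is.na(tr) || tr <= 0)) tr <- 1.0
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  grid <- make_grid(d[1:3], abs(hdr$pixdim[2:4]), affine = aff)
  st <- if (d[4] > 1L) slice_times_from_header(hdr, d[3], tr) else numeric(0)
  volume4d(data, grid = grid, tr = tr, slice_times = st,
           units = units_from_descrip(hdr$descrip %||% ""))
}

#' Write a volume as NIFTI-1
#'
#' The affine is stored in both sform and qform, TR in `pixdim[4]`, the
#' units tag plus a provenance note in the description field, and slice
#' timing as `slice_code`/`slice_duration` when the pattern is a standard
#' sequential or alternating scheme (otherwise timing is dropped with a
#' warning; NIFTI-1 cannot encode arbitrary per-slice times).
#'
#' @param vol A [volume4d()].
#' @param path Output path (`.nii` or `.nii.gz`); single-volume series are
#'   written with a 3D shape.
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop2("directory is not writable: %s", dirname(path))
  data <- vol$data
  if (dim(data)[4] == 1L) dim(data) <- dim(data)[1:3]
  img <- RNifti::asNifti(data, datatype = "double")
  descrip <- sprintf("units=%s %s", vol$units, provenance_note("write_nifti"))
  hdr <- list(pixdim = c(-1, vol$grid$voxel_size, vol$tr, 0, 0, 0),
              descrip = substr(descrip, 1, 79))
  if (length(vol$slice_times) && diff(range(vol$slice_times)) > 1e-9) {
    st <- vol$slice_times
    nz <- length(st)
    dur <- if (nz > 1) sort(st)[2] - sort(st)[1] else 0
    code <- 0L
    if (dur > 0) {
      if (max(abs(st - (seq_len(nz) - 1) * dur)) < 1e-6) code <- 1L
      else if (max(abs(st - (nz - seq_len(nz)) * dur)) < 1e-6) code <- 2L
      else {
        alt <- numeric(nz); alt[c(seq(1, nz, 2), seq(2, nz, 2))] <- (seq_len(nz) - 1) * dur
        if (max(abs(st - alt)) < 1e-6) code <- 3L
      }
    }
    if (code > 0L) {
      hdr$slice_code <- code; hdr$slice_duration <- dur
      hdr$slice_start <- 0L; hdr$slice_end <- nz - 1L; hdr$dim_info <- 48L
    } else {
      warn2("slice timing pattern not encodable in NIFTI-1; dropped on write")
    }
  }
  img <- RNifti::updateNifti(img, hdr)
  aff <- structure(vol$grid$affine, code = 2L)
  RNifti::`sform<-`(img, aff) -> img
  RNifti::`qform<-`(img, aff) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}
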