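#' Spatial sampling grid
#'
#' A `grid3d` describes the spatial geometry of a volume: matrix dimensions,
#' voxel size in mm, and the affine mapping 0-based voxel indices to world
#' coordinates in RAS mm.  World space is RAS throughout the package:
#' +x = right, +y = anterior, +z = superior.
#'
#' @param dims Integer triple (nx, ny, nz), each >= 1.
#' @param voxel_size Positive mm triple.  Ignored when `affine` is supplied
#'   with scaling built in; when `affine` is `NULL` an axis-aligned affine is
#'   constructed with the volume centred on the world origin.
#' @param affine 4x4 voxel-index -> world-mm map, or `NULL`.
#' @param orientation 3-letter axis code (informational), default `"RAS"`.
#' @return An object of class `grid3d`.
#' @examples
#' g <- make_grid(c(32, 32, 20), c(3, 3, 4))
#' grid_voxel_to_world(g, c(0, 0, 0))
#' @export
make_grid <- function(dims, voxel_size = c(1, 1, 1), affine = NULL,
                      orientation = "RAS") {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop2("grid dims must be 3 integers >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop2("voxel sizes must be 3 positive mm values")
  if (is.null(affine)) {
    affine <- diag(4)
    affine[cbind(1:3, 1:3)] <- voxel_size
    # centre the grid on the world origin
    affine[1:3, 4] <- -voxel_size * (dims - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine[1:3, 1:3])) < 1e-12)
    stop2("grid affine must be an invertible 4x4 matrix")
  structure(list(dims = dims, voxel_size = voxel_size,
                 affine = affine, orientation = orientation),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d %dx%dx%d, voxels %.3gx%.3gx%.3g mm, %s>\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$orientation))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) && max(abs(a$affine - b$affine)) <= tol
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based, matching the affine convention of the NIfTI
#' standard.
#'
#' @param grid A `grid3d`.
#' @param ijk,xyz Length-3 vector or 3-row matrix of coordinates.
#' @return Matrix (3 x n) of mapped coordinates (vector for single points).
#' @export
grid_voxel_to_world <- function(grid, ijk) {
  ijk <- if (is.matrix(ijk)) ijk else matrix(ijk, nrow = 3)
  out <- grid$affine[1:3, 1:3] %*% ijk + grid$affine[1:3, 4]
  if (ncol(out) == 1L) drop(out) else out
}

#' @rdname grid_voxel_to_world
#' @export
grid_world_to_voxel <- function(grid, xyz) {
  xyz <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 3)
  inv <- solve(grid$affine)
  out <- inv[1:3, 1:3] %*% xyz + inv[1:3, 4]
  if (ncol(out) == 1L) drop(out) else out
}
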