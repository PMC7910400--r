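#' Build a reconstruction grid
#'
#' Defines the voxel grid of a reconstructed PET volume. The transaxial
#' voxel size is the exact division of the reconstructed in-plane field of
#' view by the in-plane matrix size; the axial voxel size equals the slice
#' thickness. World coordinates are in mm with a voxel-centre convention:
#' the centre of voxel `(i, j, k)` (1-based indices) lies at
#' `origin + (c(i, j, k) - 1) * voxel_size`. By default the grid is centred
#' on the world origin.
#'
#' @param matrix Integer vector of voxel counts, length 3 `(nx, ny, nz)`.
#'   A single value is recycled to an isotropic cube.
#' @param in_plane_fov Reconstructed in-plane field of view in mm (applies
#'   to both transaxial axes).
#' @param slice_thickness Axial voxel size in mm.
#' @param origin Optional world coordinate (mm) of the centre of voxel
#'   `(1, 1, 1)`. Default centres the grid at `(0, 0, 0)`.
#' @return An object of class `grid_spec` with fields `matrix`,
#'   `voxel_size` (mm triple), `in_plane_fov`, `slice_thickness`, `origin`.
#' @examples
#' g <- build_grid(c(256, 256, 89), in_plane_fov = 356, slice_thickness = 2.78)
#' round(g$voxel_size, 3)  # 1.391 1.391 2.780
#' @export
build_grid <- function(matrix, in_plane_fov, slice_thickness, origin = NULL) {
  if (length(matrix) == 1L) matrix <- rep(matrix, 3L)
  if (length(matrix) != 3L) stop("'matrix' must have length 1 or 3")
  matrix <- as.integer(matrix)
  if (anyNA(matrix) || any(matrix < 1L))
    stop("invalid grid spec: matrix entries must be >= 1")
  if (!is.finite(in_plane_fov) || in_plane_fov <= 0)
    stop("invalid grid spec: in_plane_fov must be > 0")
  if (!is.finite(slice_thickness) || slice_thickness <= 0)
    stop("invalid grid spec: slice_thickness must be > 0")
  voxel_size <- c(in_plane_fov / matrix[1L], in_plane_fov / matrix[2L],
                  slice_thickness)
  if (is.null(origin)) {
    origin <- -voxel_size * (matrix - 1) / 2
  } else {
    if (length(origin) != 3L || !all(is.finite(origin)))
      stop("invalid grid spec: origin must be a finite mm triple")
  }
  structure(
    list(matrix = matrix, voxel_size = voxel_size,
         in_plane_fov = in_plane_fov, slice_thickness = slice_thickness,
         origin = origin),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              x$matrix[1], x$matrix[2], x$matrix[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Voxel-centre world coordinates along one grid axis
#'
#' @param grid A `grid_spec`.
#' @param axis Axis index (1 = x, 2 = y, 3 = z/axial).
#' @return Numeric vector of mm coordinates, one per voxel along the axis.
#' @export
grid_axis_coords <- function(grid, axis) {
  stopifnot(inherits(grid, "grid_spec"), axis %in% 1:3)
  grid$origin[axis] + (seq_len(grid$matrix[axis]) - 1) * grid$voxel_size[axis]
}

#' Nearest voxel index for a world coordinate
#'
#' @param grid A `grid_spec`.
#' @param xyz World coordinate in mm (length 3) or an n x 3 matrix.
#' @return Integer (matrix of) 1-based voxel indices; coordinates outside
#'   the grid give indices outside `1:matrix`.
#' @export
world_to_voxel <- function(grid, xyz) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(dim(xyz))) xyz <- base::matrix(xyz, nrow = 1L)
  idx <- sweep(sweep(xyz, 2L, grid$origin, "-"), 2L, grid$voxel_size, "/")
  round(idx) + 1L
}

#' Construct a 3-D image
#'
#' Container for a voxel grid of activity concentrations (kBq/ml).
#'
#' @param values 3-D numeric array matching `grid$matrix`.
#' @param grid A `grid_spec`.
#' @return An object of class `image3d` with fields `values`, `grid`.
#' @export
image3d <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (!all(dim(values) == grid$matrix))
    stop("image dimensions do not match grid")
  if (!all(is.finite(values))) stop("image values must be finite")
  structure(list(values = values, grid = grid), class = "image3d")
}

#' Construct a 4-D (dynamic) image
#'
#' @param values 4-D numeric array, `grid$matrix` by number of frames.
#' @param grid A `grid_spec`.
#' @param schedule A `frame_schedule` whose frame count matches `dim(values)[4]`.
#' @return An object of class `image4d` with fields `values`, `grid`,
#'   `schedule`.
#' @export
image4d <- function(values, grid, schedule) {
  stopifnot(inherits(grid, "grid_spec"), inherits(schedule, "frame_schedule"))
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("'values' must be a 4-D array")
  if (!all(dim(values)[1:3] == grid$matrix))
    stop("image dimensions do not match grid")
  if (dim(values)[4L] != nrow(schedule))
    stop("frame count does not match schedule")
  if (!all(is.finite(values))) stop("image values must be finite")
  structure(list(values = values, grid = grid, schedule = schedule),
            class = "image4d")
}

#' @export
print.image3d <- function(x, ...) {
  cat(sprintf("image3d: %s voxels, range [%.3g, %.3g] kBq/ml\n",
              paste(dim(x$values), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.image4d <- function(x, ...) {
  cat(sprintf("image4d: %s voxels x %d frames\n",
              paste(dim(x$values)[1:3], collapse = " x "),
              dim(x$values)[4L]))
  invisible(x)
}
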