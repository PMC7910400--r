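#' Circular (single-slice) region of interest
#'
#' A planar circular ROI on one transaxial slice, as used for the
#' NEMA-style single-slice sphere and background analysis.
#'
#' @param center In-plane world mm pair `(x, y)`.
#' @param diameter ROI diameter in mm (> 0).
#' @param slice_index 1-based axial slice index.
#' @return An object of class `circular_roi`.
#' @export
circular_roi <- function(center, diameter, slice_index) {
  if (length(center) != 2L || !all(is.finite(center)))
    stop("circular ROI center must be a finite mm pair")
  if (!is.finite(diameter) || diameter <= 0)
    stop("ROI diameter must be > 0")
  slice_index <- as.integer(slice_index)
  if (is.na(slice_index) || slice_index < 1L)
    stop("slice_index must be a positive integer")
  structure(list(center = as.numeric(center), diameter = diameter,
                 slice_index = slice_index),
            class = "circular_roi")
}

#' Spherical volume of interest
#'
#' @param center World mm triple.
#' @param diameter VOI diameter in mm (> 0).
#' @return An object of class `spherical_voi`.
#' @export
spherical_voi <- function(center, diameter) {
  if (length(center) != 3L || !all(is.finite(center)))
    stop("VOI center must be a finite mm triple")
  if (!is.finite(diameter) || diameter <= 0)
    stop("VOI diameter must be > 0")
  structure(list(center = as.numeric(center), diameter = diameter),
            class = "spherical_voi")
}

#' Voxel mask
#'
#' Binary voxel membership stored as sorted linear indices into the grid
#' array, with the grid dimensions attached.
#'
#' @param idx Integer vector of linear voxel indices (1-based).
#' @param grid A [build_grid()] spec.
#' @return An object of class `roi_mask` with fields `idx`, `dim`,
#'   `voxel_count`.
#' @export
roi_mask <- function(idx, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  idx <- sort(unique(as.integer(idx)))
  if (!length(idx)) stop("geometry error: empty mask")
  if (idx[1L] < 1L || idx[length(idx)] > prod(grid$matrix))
    stop("geometry error: mask indices outside grid")
  structure(list(idx = idx, dim = grid$matrix, voxel_count = length(idx)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %d voxels in a %s grid\n", x$voxel_count,
              paste(x$dim, collapse = " x ")))
  invisible(x)
}

mask_values <- function(img, mask) img$values[mask$idx]

#' Rasterize a circular ROI to a voxel mask
#'
#' Membership is binary by the voxel-centre-within-circle rule on the
#' single slice (no fractional weighting), matching common ROI-tool
#' behaviour.
#'
#' @param roi A [circular_roi()].
#' @param grid A [build_grid()] spec.
#' @return A [roi_mask()].
#' @export
rasterize_circular_roi <- function(roi, grid) {
  stopifnot(inherits(roi, "circular_roi"), inherits(grid, "grid_spec"))
  if (roi$slice_index > grid$matrix[3L])
    stop("geometry error: slice outside image")
  inplane <- circle_inplane_indices(roi$center, roi$diameter, grid)
  if (!nrow(inplane)) stop("geometry error: empty mask")
  idx <- inplane[, 1L] + (inplane[, 2L] - 1L) * grid$matrix[1L] +
    (roi$slice_index - 1L) * grid$matrix[1L] * grid$matrix[2L]
  roi_mask(idx, grid)
}

# In-plane (i, j) voxel indices whose centres fall inside the circle.
circle_inplane_indices <- function(center, diameter, grid) {
  r <- diameter / 2
  xs <- grid_axis_coords(grid, 1L)
  ys <- grid_axis_coords(grid, 2L)
  ii <- which(abs(xs - center[1L]) <= r)
  jj <- which(abs(ys - center[2L]) <= r)
  if (!length(ii) || !length(jj))
    return(matrix(integer(), ncol = 2L))
  d2 <- outer((xs[ii] - center[1L])^2, (ys[jj] - center[2L])^2, "+")
  hit <- which(d2 <= r^2, arr.ind = TRUE)
  cbind(ii[hit[, 1L]], jj[hit[, 2L]])
}

#' Rasterize a spherical VOI to a voxel mask
#'
#' Binary voxel-centre-within-sphere membership in 3-D.
#'
#' @param voi A [spherical_voi()].
#' @param grid A [build_grid()] spec.
#' @return A [roi_mask()].
#' @export
rasterize_spherical_voi <- function(voi, grid) {
  stopifnot(inherits(voi, "spherical_voi"), inherits(grid, "grid_spec"))
  r <- voi$diameter / 2
  xs <- grid_axis_coords(grid, 1L)
  ys <- grid_axis_coords(grid, 2L)
  zs <- grid_axis_coords(grid, 3L)
  ii <- which(abs(xs - voi$center[1L]) <= r)
  jj <- which(abs(ys - voi$center[2L]) <= r)
  kk <- which(abs(zs - voi$center[3L]) <= r)
  if (!length(ii) || !length(jj) || !length(kk))
    stop("geometry error: empty mask")
  d2 <- outer(outer((xs[ii] - voi$center[1L])^2,
                    (ys[jj] - voi$center[2L])^2, "+"),
              (zs[kk] - voi$center[3L])^2, "+")
  hit <- which(d2 <= r^2, arr.ind = TRUE)
  if (!nrow(hit)) stop("geometry error: empty mask")
  idx <- ii[hit[, 1L]] + (jj[hit[, 2L]] - 1L) * grid$matrix[1L] +
    (kk[hit[, 3L]] - 1L) * grid$matrix[1L] * grid$matrix[2L]
  roi_mask(idx, grid)
}

#' Find the transaxial slice in which a sphere is most visible
#'
#' Operationalizes the NEMA "most visible plane": among slices within one
#' sphere radius of the geometric centre slice, returns the slice whose
#' in-ROI mean (circular ROI of the sphere's inner diameter at the sphere's
#' in-plane centre) is maximal for hot spheres or minimal for cold spheres.
#' Ties go to the slice nearest the geometric centre, then to the lower
#' index.
#'
#' @param img An [image3d()].
#' @param sphere A [sphere_spec()].
#' @param polarity `"hot"` or `"cold"`.
#' @return 1-based slice index.
#' @export
find_most_visible_slice <- function(img, sphere, polarity = c("hot", "cold")) {
  stopifnot(inherits(img, "image3d"), inherits(sphere, "sphere_spec"))
  polarity <- match.arg(polarity)
  grid <- img$grid
  zs <- grid_axis_coords(grid, 3L)
  if (sphere$center[3L] < zs[1L] - grid$voxel_size[3L] / 2 ||
      sphere$center[3L] > zs[length(zs)] + grid$voxel_size[3L] / 2)
    stop("geometry error: sphere centre outside image")
  center_slice <- which.min(abs(zs - sphere$center[3L]))
  r <- sphere$inner_diameter / 2
  candidates <- which(abs(zs - sphere$center[3L]) <= r)
  if (!length(candidates)) candidates <- center_slice
  inplane <- circle_inplane_indices(sphere$center[1:2], sphere$inner_diameter,
                                    grid)
  if (!nrow(inplane)) stop("geometry error: sphere ROI empty on this grid")
  base_idx <- inplane[, 1L] + (inplane[, 2L] - 1L) * grid$matrix[1L]
  page <- grid$matrix[1L] * grid$matrix[2L]
  means <- vapply(candidates,
                  function(k) mean(img$values[base_idx + (k - 1L) * page]), 0)
  score <- if (polarity == "hot") means else -means
  best <- max(score)
  tied <- candidates[score >= best - 1e-12 * max(abs(best), 1)]
  tied[order(abs(zs[tied] - sphere$center[3L]), tied)][1L]
}

#' Build the background ROI grid
#'
#' Places 12 circular background ROIs per sphere size, with centres equally
#' spaced on a circle of `layout_radius` in the central plane, replicated
#' at axial offsets of +-1 cm and +-2 cm (converted to the nearest slice),
#' for a total of 60 background ROIs per sphere size. ROI centres are
#' concentric across sphere sizes. Every ROI must lie inside the cylinder
#' and keep at least `margin` mm between its edge and every sphere surface;
#' an infeasible layout raises a geometry error listing the violating ROIs.
#'
#' @param phantom A [phantom_spec()].
#' @param grid A [build_grid()] spec.
#' @param central_slice 1-based slice index of the central plane (the plane
#'   of the single-slice sphere ROIs).
#' @param layout_radius Radius (mm) of the circle of ROI centres.
#' @param margin Minimum clearance (mm) between any background ROI edge and
#'   any sphere surface.
#' @param offsets_mm Axial plane offsets in mm (default 0, +-10, +-20).
#' @param start_angle_deg Angular position of the first ROI centre.
#' @return An object of class `background_grid`: a list with `rois` (one
#'   list of 60 [circular_roi()] per sphere size, named by diameter),
#'   `diameters`, and layout metadata including the slice indices actually
#'   used for each plane offset.
#' @export
build_background_grid <- function(phantom, grid, central_slice,
                                  layout_radius = 85, margin = 15,
                                  offsets_mm = c(-20, -10, 0, 10, 20),
                                  start_angle_deg = 15) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(grid, "grid_spec"))
  central_slice <- as.integer(central_slice)
  if (central_slice < 1L || central_slice > grid$matrix[3L])
    stop("geometry error: central_slice outside image")
  diameters <- vapply(phantom$spheres, function(s) s$inner_diameter, 0)
  d_max <- max(diameters)
  if (2 * layout_radius * sin(pi / 12) < d_max)
    stop("geometry error: layout_radius too small for 12 non-overlapping ",
         "ROIs of the largest sphere diameter")
  ang <- start_angle_deg * pi / 180 + (0:11) * pi / 6
  cx <- layout_radius * cos(ang)
  cy <- layout_radius * sin(ang)
  zs <- grid_axis_coords(grid, 3L)
  z0 <- zs[central_slice]
  slices <- vapply(offsets_mm,
                   function(o) which.min(abs(zs - (z0 + o))), 0L)

  violations <- character()
  rois <- list()
  for (d in diameters) {
    r_roi <- d / 2
    set <- vector("list", 12L * length(slices))
    n <- 0L
    for (p in seq_along(slices)) {
      z <- zs[slices[p]]
      for (q in 1:12) {
        if (sqrt(cx[q]^2 + cy[q]^2) + r_roi > phantom$cylinder_radius ||
            abs(z) + 0 > phantom$cylinder_height / 2)
          violations <- c(violations, sprintf(
            "ROI d=%.3g at angle %d, plane %+g mm: outside cylinder",
            d, q, offsets_mm[p]))
        for (s in phantom$spheres) {
          dxy <- sqrt((cx[q] - s$center[1L])^2 + (cy[q] - s$center[2L])^2)
          lateral <- max(dxy - r_roi, 0)
          clearance <- sqrt(lateral^2 + (z - s$center[3L])^2) -
            s$inner_diameter / 2
          if (clearance < margin)
            violations <- c(violations, sprintf(
              "ROI d=%.3g at angle %d, plane %+g mm: %.3g mm from sphere d=%.3g (margin %.3g)",
              d, q, offsets_mm[p], clearance, s$inner_diameter, margin))
        }
        n <- n + 1L
        set[[n]] <- circular_roi(c(cx[q], cy[q]), d, slices[p])
      }
    }
    rois[[sprintf("%.1f", d)]] <- set
  }
  if (length(violations))
    stop("geometry error: infeasible background layout:\n  ",
         paste(unique(violations), collapse = "\n  "))
  structure(list(rois = rois, diameters = diameters,
                 layout_radius = layout_radius, margin = margin,
                 offsets_mm = offsets_mm, slices = slices,
                 start_angle_deg = start_angle_deg,
                 central_slice = central_slice),
            class = "background_grid")
}

#' Build the full ROI set for a phantom image
#'
#' For each sphere: finds the most visible slice, places the single-slice
#' circular ROI (diameter equal to the sphere inner diameter) and the
#' matching spherical VOI; then builds the 60-ROI background grid per
#' sphere size on the central plane of the sphere ring.
#'
#' @param img An [image3d()] of the phantom.
#' @param phantom The [phantom_spec()] that generated it.
#' @param layout_radius,margin,offsets_mm,start_angle_deg Passed to
#'   [build_background_grid()].
#' @return An object of class `roi_set`: `spheres` (per sphere: spec,
#'   polarity, slice, `roi`, `voi`) and `background` (a `background_grid`).
#' @export
build_roi_set <- function(img, phantom, layout_radius = 85, margin = 15,
                          offsets_mm = c(-20, -10, 0, 10, 20),
                          start_angle_deg = 15) {
  stopifnot(inherits(img, "image3d"), inherits(phantom, "phantom_spec"))
  spheres <- lapply(phantom$spheres, function(s) {
    polarity <- if (s$concentration > 0) "hot" else "cold"
    slice <- find_most_visible_slice(img, s, polarity)
    list(spec = s, polarity = polarity, slice = slice,
         roi = circular_roi(s$center[1:2], s$inner_diameter, slice),
         voi = spherical_voi(s$center, s$inner_diameter))
  })
  central <- as.integer(round(stats::median(
    vapply(spheres, function(x) x$slice, 0L))))
  bg <- build_background_grid(phantom, img$grid, central,
                              layout_radius = layout_radius, margin = margin,
                              offsets_mm = offsets_mm,
                              start_angle_deg = start_angle_deg)
  structure(list(spheres = spheres, background = bg, grid = img$grid,
                 background_concentration = phantom$background_concentration),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set: %d spheres, %d background ROIs per sphere size\n",
              length(x$spheres), length(x$background$rois[[1L]])))
  invisible(x)
}
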