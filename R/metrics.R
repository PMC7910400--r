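#' Hot-sphere recovery coefficient
#'
#' The fraction of true hot-sphere contrast recovered in the image:
#' \deqn{\mathrm{RC_{hot}} = \frac{C_{sphere}/C_{background} - 1}
#'   {A_{hot}/A_{background} - 1} \times 100\%}
#' where `c_sphere` and `c_background` are the measured sphere-ROI mean and
#' background level, and `a_hot`/`a_background` the true concentrations.
#' Values above 100% are permitted (Gibbs edge overshoot under PSF
#' reconstruction) and are not clamped.
#'
#' @param c_sphere Measured mean concentration in the sphere ROI/VOI,
#'   kBq/ml.
#' @param c_background Measured background level (mean of the background
#'   ROI means), kBq/ml (> 0).
#' @param a_hot,a_background True hot-sphere and background concentrations,
#'   kBq/ml.
#' @return Recovery coefficient in percent.
#' @examples
#' rc_hot(2.44, 1, 3.88, 1)  # 50%
#' @export
rc_hot <- function(c_sphere, c_background, a_hot, a_background) {
  stopifnot(is.finite(c_sphere), is.finite(c_background),
            is.finite(a_hot), is.finite(a_background))
  if (c_background <= 0) stop("c_background must be > 0")
  if (a_background <= 0) stop("a_background must be > 0")
  true_ratio <- a_hot / a_background
  if (abs(true_ratio - 1) < 1e-12)
    stop("undefined contrast: true hot/background ratio equals 1")
  (c_sphere / c_background - 1) / (true_ratio - 1) * 100
}

#' Cold-sphere recovery coefficient
#'
#' \deqn{\mathrm{RC_{cold}} = \left(1 - C_{sphere}/C_{background}\right)
#'   \times 100\%}
#'
#' @param c_sphere Measured mean concentration in the cold-sphere ROI/VOI,
#'   kBq/ml.
#' @param c_background Measured background level, kBq/ml (> 0).
#' @return Recovery coefficient in percent (100% = perfectly cold).
#' @export
rc_cold <- function(c_sphere, c_background) {
  stopifnot(is.finite(c_sphere), is.finite(c_background))
  if (c_background <= 0) stop("c_background must be > 0")
  (1 - c_sphere / c_background) * 100
}

#' Percent background variability
#'
#' Coefficient of variation of the K background-ROI means (sample standard
#' deviation, denominator K - 1) relative to their mean, in percent. With
#' the standard layout K = 60 per sphere size.
#'
#' @param background_roi_means Numeric vector of per-ROI mean
#'   concentrations, kBq/ml (length >= 2).
#' @return Percent background variability.
#' @examples
#' bg_variability(c(9, 10, 11))  # 10%
#' @export
bg_variability <- function(background_roi_means) {
  if (length(background_roi_means) < 2L)
    stop("need at least 2 background ROI means")
  m <- mean(background_roi_means)
  if (abs(m) < .Machine$double.eps)
    stop("undefined: background mean is zero")
  stats::sd(background_roi_means) / m * 100
}

#' Voxel-level noise
#'
#' Coefficient of variation of individual voxel values within the pooled
#' background ROIs (union of voxels across the ROIs of one sphere size),
#' in percent. The denominator is the mean over the same pooled voxels.
#'
#' @param background_masks A [roi_mask()] or list of masks to pool.
#' @param img An [image3d()].
#' @return Percent voxel noise.
#' @export
voxel_noise <- function(background_masks, img) {
  stopifnot(inherits(img, "image3d"))
  if (inherits(background_masks, "roi_mask"))
    background_masks <- list(background_masks)
  if (!length(background_masks) ||
      !all(vapply(background_masks, inherits, TRUE, "roi_mask")))
    stop("geometry error: background_masks must be roi_mask objects")
  idx <- unique(unlist(lapply(background_masks, function(m) m$idx)))
  if (length(idx) < 2L) stop("geometry error: fewer than 2 pooled voxels")
  v <- img$values[idx]
  m <- mean(v)
  if (abs(m) < .Machine$double.eps)
    stop("undefined: pooled background mean is zero")
  stats::sd(v) / m * 100
}

# Background measurement for one sphere size: the 60 single-slice ROI means,
# their mean and sample SD, and the pooled voxel-level CoV inputs.
background_measurement <- function(img, bg_grid, diameter) {
  key <- sprintf("%.1f", diameter)
  rois <- bg_grid$rois[[key]]
  if (is.null(rois)) stop("no background ROIs for diameter ", diameter)
  masks <- lapply(rois, rasterize_circular_roi, grid = img$grid)
  means <- vapply(masks, function(m) mean(mask_values(img, m)), 0)
  list(means = means, c_background = mean(means),
       sd_means = stats::sd(means), masks = masks)
}

#' Full image-quality analysis of a phantom image
#'
#' Measures every sphere with both the single-slice circular ROI and the
#' spherical VOI, computes hot/cold recovery coefficients against the true
#' concentrations, percent background variability from the 60 background
#' ROI means per sphere size, and pooled voxel noise per sphere size.
#'
#' @param img An [image3d()] of the phantom.
#' @param roi_set A [build_roi_set()] result.
#' @param truth Optional list with `a_hot` and `a_background` (true kBq/ml
#'   concentrations); defaults to the generating phantom's values stored in
#'   the ROI set's sphere specs.
#' @return A tidy data frame with one row per sphere and analysis mode:
#'   `diameter_mm`, `polarity`, `mode` (`single_slice`/`spherical_voi`),
#'   `c_sphere`, `c_background`, `sd_background_means`, `rc_pct`,
#'   `bg_variability_pct`, `voxel_noise_pct`.
#' @export
analyze_phantom <- function(img, roi_set, truth = NULL) {
  stopifnot(inherits(img, "image3d"), inherits(roi_set, "roi_set"))
  rows <- list()
  for (sp in roi_set$spheres) {
    d <- sp$spec$inner_diameter
    bg <- background_measurement(img, roi_set$background, d)
    vnoise <- voxel_noise(bg$masks, img)
    bgvar <- bg_variability(bg$means)
    a_hot <- if (is.null(truth)) sp$spec$concentration else truth$a_hot
    a_bg <- if (is.null(truth)) roi_set$background_concentration
            else truth$a_background
    if (is.null(a_bg)) stop("no true background concentration; pass 'truth'")
    for (mode in c("single_slice", "spherical_voi")) {
      mask <- if (mode == "single_slice")
        rasterize_circular_roi(sp$roi, img$grid)
      else rasterize_spherical_voi(sp$voi, img$grid)
      c_sphere <- mean(mask_values(img, mask))
      rc <- if (sp$polarity == "hot")
        rc_hot(c_sphere, bg$c_background, a_hot, a_bg)
      else rc_cold(c_sphere, bg$c_background)
      rows[[length(rows) + 1L]] <- data.frame(
        diameter_mm = d, polarity = sp$polarity, mode = mode,
        c_sphere = c_sphere, c_background = bg$c_background,
        sd_background_means = bg$sd_means, rc_pct = rc,
        bg_variability_pct = bgvar, voxel_noise_pct = vnoise)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recovery-versus-noise trajectory over an image series
#'
#' Computes the full image-quality analysis for each image in an
#' iteration-indexed series (e.g. increasing OSEM iterations) and stacks
#' the results with an `iteration` column. No smoothing is applied across
#' iterations.
#'
#' @param image_series List of [image3d()] objects on a common grid.
#' @param roi_set A [build_roi_set()] result.
#' @param truth List with `a_hot`, `a_background`.
#' @return Data frame: `iteration` plus the [analyze_phantom()] columns.
#' @export
rc_noise_trajectory <- function(image_series, roi_set, truth) {
  if (!length(image_series)) stop("need at least one image")
  if (!all(vapply(image_series, inherits, TRUE, "image3d")))
    stop("image_series must contain image3d objects")
  dims <- lapply(image_series, function(im) im$grid$matrix)
  if (!all(vapply(dims, identical, TRUE, dims[[1L]])))
    stop("inconsistent grids in image series")
  out <- lapply(seq_along(image_series), function(i) {
    cbind(iteration = i,
          analyze_phantom(image_series[[i]], roi_set, truth))
  })
  do.call(rbind, out)
}

#' Line profile through an image
#'
#' Samples the image along a straight segment at a spacing equal to the
#' smallest in-plane voxel size, using nearest-voxel lookup (single voxel
#' width, no interpolation), and normalizes the values by the injected
#' activity.
#'
#' @param img An [image3d()].
#' @param start,end World mm triples of the segment endpoints (within the
#'   image).
#' @param injected_activity Injected activity in MBq (> 0).
#' @return A data frame of class `line_profile` with columns `position_mm`
#'   (distance from `start`, strictly increasing) and `value` (kBq/ml per
#'   MBq injected).
#' @export
line_profile <- function(img, start, end, injected_activity) {
  stopifnot(inherits(img, "image3d"),
            length(start) == 3L, length(end) == 3L)
  if (!is.finite(injected_activity) || injected_activity <= 0)
    stop("injected_activity must be > 0")
  len <- sqrt(sum((end - start)^2))
  if (len <= 0) stop("zero-length profile segment")
  spacing <- min(img$grid$voxel_size[1:2])
  pos <- seq(0, len, by = spacing)
  dir <- (end - start) / len
  pts <- cbind(start[1L] + pos * dir[1L],
               start[2L] + pos * dir[2L],
               start[3L] + pos * dir[3L])
  vox <- world_to_voxel(img$grid, pts)
  if (any(vox < 1L) || any(sweep(vox, 2L, img$grid$matrix, ">") ))
    stop("geometry error: profile segment leaves the image")
  idx <- vox[, 1L] + (vox[, 2L] - 1L) * img$grid$matrix[1L] +
    (vox[, 3L] - 1L) * prod(img$grid$matrix[1:2])
  out <- data.frame(position_mm = pos,
                    value = img$values[idx] / injected_activity)
  class(out) <- c("line_profile", "data.frame")
  out
}

#' Convert scanner sensitivity between reporting conventions
#'
#' NEMA sensitivity reported in cps/kBq converts to percent as
#' `cps_per_kbq / 1000 * 100`, i.e. detected counts per decay. Some systems
#' normalize by only the in-FOV portion of the 70 cm line source rather
#' than its entire length; passing the two lengths rescales accordingly:
#' `percent = cps_per_kbq / 1000 * (source_length / normalization_length)
#' * 100`.
#'
#' @param cps_per_kbq Sensitivity in counts/s per kBq (>= 0).
#' @param source_length Full line-source length in cm (> 0), 70 by
#'   convention.
#' @param normalization_length Length in cm over which the activity is
#'   normalized (> 0); equal to `source_length` for the plain unit
#'   conversion, or the in-FOV length (e.g. 25) for the in-FOV convention.
#' @return Sensitivity in percent.
#' @examples
#' sensitivity_percent(23.3, 70, 70)  # 2.33%
#' sensitivity_percent(23.3, 70, 25)  # 6.52%
#' @export
sensitivity_percent <- function(cps_per_kbq, source_length = 70,
                                normalization_length = source_length) {
  stopifnot(is.finite(cps_per_kbq), cps_per_kbq >= 0,
            is.finite(source_length), source_length > 0,
            is.finite(normalization_length), normalization_length > 0)
  cps_per_kbq / 1000 * (source_length / normalization_length) * 100
}
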