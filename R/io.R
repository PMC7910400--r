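#' Write an image as NIfTI-1
#'
#' Writes the voxel array with correct `pixdim` (mm voxel sizes; the frame
#' axis of a 4-D image gets the frame durations' total in seconds only via
#' the sidecar, not the NIfTI header). Grid origin is stored in the qform
#' translation.
#'
#' @param img An [image3d()] or [image4d()].
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param sidecar If `TRUE` (default), also writes `<path>.json` with the
#'   grid (and schedule) parameters for provenance.
#' @return `path`, invisibly.
#' @export
write_image_nifti <- function(img, path, sidecar = TRUE) {
  stopifnot(inherits(img, "image3d") || inherits(img, "image4d"))
  g <- img$grid
  ni <- RNifti::asNifti(img$values)
  ndim <- length(dim(img$values))
  RNifti::pixdim(ni) <- c(g$voxel_size, if (ndim == 4L) 1)
  xform <- diag(c(g$voxel_size, 1))
  xform[1:3, 4L] <- g$origin
  RNifti::qform(ni) <- structure(xform, code = 2L)
  RNifti::writeNifti(ni, path)
  if (sidecar) {
    meta <- list(matrix = g$matrix, voxel_size_mm = g$voxel_size,
                 in_plane_fov_mm = g$in_plane_fov,
                 slice_thickness_mm = g$slice_thickness,
                 origin_mm = g$origin)
    if (inherits(img, "image4d"))
      meta$frame_schedule_s <- list(start = img$schedule$start,
                                    duration = img$schedule$duration)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a NIfTI image
#'
#' Rebuilds an [image3d()] or [image4d()] from a NIfTI file written by
#' [write_image_nifti()] (or any NIfTI with mm `pixdim`). The grid origin
#' is taken from the qform translation when present, else the grid is
#' centred on the world origin. Reading a 4-D file requires the frame
#' `schedule`.
#'
#' @param path NIfTI file path.
#' @param schedule A [frame_schedule()] for 4-D images.
#' @return An [image3d()] or [image4d()].
#' @export
read_image_nifti <- function(path, schedule = NULL) {
  ni <- RNifti::readNifti(path)
  values <- array(as.numeric(ni), dim = dim(ni))
  hdr <- RNifti::niftiHeader(ni)
  voxel <- hdr$pixdim[2:4]
  d <- dim(values)
  xf <- try(RNifti::qform(ni), silent = TRUE)
  origin <- if (!inherits(xf, "try-error") && is.matrix(xf) &&
                any(xf[1:3, 4L] != 0)) xf[1:3, 4L] else NULL
  grid <- build_grid(d[1:3], in_plane_fov = voxel[1L] * d[1L],
                     slice_thickness = voxel[3L], origin = origin)
  if (length(d) == 3L) return(image3d(values, grid))
  if (is.null(schedule))
    stop("reading a 4-D image requires a frame schedule")
  image4d(values, grid, schedule)
}

#' Export an ROI set as a NIfTI label map
#'
#' Sphere ROIs get labels 1..n (in sphere order); optionally one sphere
#' size's background ROIs get label `n + 1`. Intended for visual
#' inspection of ROI placement.
#'
#' @param roi_set A [build_roi_set()] result.
#' @param path Output NIfTI path.
#' @param mode `"single_slice"` or `"spherical_voi"` sphere masks.
#' @param background_diameter Optional sphere diameter (mm) whose
#'   background ROIs to include.
#' @return `path`, invisibly.
#' @export
write_roi_labelmap <- function(roi_set, path, mode = c("single_slice",
                                                       "spherical_voi"),
                               background_diameter = NULL) {
  mode <- match.arg(mode)
  grid <- roi_set$grid
  lab <- array(0L, dim = grid$matrix)
  for (i in seq_along(roi_set$spheres)) {
    sp <- roi_set$spheres[[i]]
    m <- if (mode == "single_slice") rasterize_circular_roi(sp$roi, grid)
         else rasterize_spherical_voi(sp$voi, grid)
    lab[m$idx] <- i
  }
  if (!is.null(background_diameter)) {
    key <- sprintf("%.1f", background_diameter)
    for (roi in roi_set$background$rois[[key]]) {
      m <- rasterize_circular_roi(roi, grid)
      lab[m$idx] <- length(roi_set$spheres) + 1L
    }
  }
  write_image_nifti(image3d(lab + 0, grid), path, sidecar = FALSE)
}

#' Serialize an ROI set to JSON
#'
#' Writes sphere ROI/VOI centres, diameters and slice indices plus the
#' background layout (centres, diameters, slice indices per plane) to a
#' structured JSON file.
#'
#' @param roi_set A [build_roi_set()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_roi_set <- function(roi_set, path) {
  bg <- roi_set$background
  spheres <- lapply(roi_set$spheres, function(sp) list(
    diameter_mm = sp$spec$inner_diameter, polarity = sp$polarity,
    center_mm = sp$spec$center, slice_index = sp$slice))
  background <- list(layout_radius_mm = bg$layout_radius,
                     margin_mm = bg$margin, offsets_mm = bg$offsets_mm,
                     slice_indices = bg$slices,
                     start_angle_deg = bg$start_angle_deg,
                     central_slice = bg$central_slice,
                     rois_per_sphere_size = length(bg$rois[[1L]]))
  jsonlite::write_json(list(spheres = spheres, background = background),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write TACs to CSV
#'
#' Tidy long format: `region`, `frame_start_s`, `frame_duration_s`,
#' `value_kbq_ml`.
#'
#' @param tacs A [tac()] or list of TACs.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tacs <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  rows <- lapply(tacs, function(tc)
    data.frame(region = tc$region, frame_start_s = tc$schedule$start,
               frame_duration_s = tc$schedule$duration,
               value_kbq_ml = tc$values))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read TACs from CSV
#'
#' Inverse of [write_tacs()].
#'
#' @param path CSV path with columns `region`, `frame_start_s`,
#'   `frame_duration_s`, `value_kbq_ml`.
#' @return Named list of [tac()] objects.
#' @export
read_tacs <- function(path) {
  df <- utils::read.csv(path)
  need <- c("region", "frame_start_s", "frame_duration_s", "value_kbq_ml")
  if (!all(need %in% names(df)))
    stop("TAC CSV must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$region), function(d) {
    d <- d[order(d$frame_start_s), ]
    tac(frame_schedule(d$frame_duration_s, start = d$frame_start_s[1L]),
        d$value_kbq_ml, region = d$region[1L])
  })
  out[unique(df$region)]
}
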