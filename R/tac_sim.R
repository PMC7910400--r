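#' Frame schedule
#'
#' Contiguous, non-overlapping acquisition frames. Stored as a data frame
#' with columns `start`, `duration` and derived `mid` (all seconds).
#'
#' @param durations Frame durations in seconds (all > 0); may be empty.
#' @param start Acquisition start time of the first frame in seconds.
#' @return A `frame_schedule` (data frame with columns `start`, `duration`,
#'   `mid`).
#' @examples
#' # 16-frame 60-min schedule used for reversible 11C tracers
#' sch <- frame_schedule(c(rep(60, 4), rep(120, 3), rep(300, 8), 600))
#' total_duration(sch)  # 60 min
#' @export
frame_schedule <- function(durations, start = 0) {
  durations <- as.numeric(durations)
  if (anyNA(durations) || any(durations <= 0))
    stop("frame durations must be positive")
  starts <- start + c(0, cumsum(durations))[seq_along(durations)]
  out <- data.frame(start = starts, duration = durations,
                    mid = starts + durations / 2)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Standard 60-minute brain PET schedules
#'
#' The two histogramming schemes used for dynamic 60-min acquisitions:
#' 16 frames (4 x 60 s, 3 x 120 s, 8 x 300 s, 1 x 600 s) for reversible
#' 11C tracers, and 17 frames (4 x 60 s, 3 x 120 s, 10 x 300 s) for FDG.
#'
#' @param type `"16-frame"` or `"17-frame"`.
#' @return A [frame_schedule()].
#' @export
brain_pet_schedule <- function(type = c("16-frame", "17-frame")) {
  type <- match.arg(type)
  if (type == "16-frame")
    frame_schedule(c(rep(60, 4), rep(120, 3), rep(300, 8), 600))
  else
    frame_schedule(c(rep(60, 4), rep(120, 3), rep(300, 10)))
}

#' Total duration of a schedule in minutes
#'
#' @param schedule A [frame_schedule()].
#' @return Total acquisition time in minutes (0 for an empty schedule).
#' @export
total_duration <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  sum(schedule$duration) / 60
}

#' Time-activity curve
#'
#' Frame-average, decay-corrected regional concentrations.
#'
#' @param schedule A [frame_schedule()].
#' @param values kBq/ml per frame, length matching the schedule.
#' @param region Region label.
#' @return An object of class `tac` with fields `schedule`, `values`,
#'   `region`.
#' @export
tac <- function(schedule, values, region = "region") {
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != nrow(schedule))
    stop("TAC length does not match schedule")
  if (!all(is.finite(values))) stop("TAC values must be finite")
  structure(list(schedule = schedule, values = values, region = region),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("tac '%s': %d frames over %.3g min, peak %.4g kBq/ml\n",
              x$region, nrow(x$schedule), total_duration(x$schedule),
              if (length(x$values)) max(x$values) else NA))
  invisible(x)
}

# Fine time grid (midpoint samples, minutes) used by the kinetic forward
# models; dt = 1 s keeps frame-average errors well below 0.5% for 60 s
# frames.
fine_grid <- function(schedule, dt = 1) {
  t_end <- max(schedule$start + schedule$duration)
  tt <- seq(dt / 2, t_end - dt / 2, by = dt)
  list(t_min = tt / 60, dt_min = dt / 60,
       frame = findInterval(tt, schedule$start))
}

frame_average <- function(fine_values, fine) {
  as.numeric(tapply(fine_values, fine$frame, mean))
}

#' Simulate a reference-region time-activity curve
#'
#' Gamma-variate bolus model `C_R(t) = amplitude * t^alpha * exp(-t/beta)`
#' (t in minutes), sampled as frame averages on a 1 s grid. The returned
#' TAC carries the continuous-curve parameters as an attribute so that
#' downstream forward models can evaluate the exact curve.
#'
#' @param schedule A [frame_schedule()].
#' @param amplitude Scale in kBq/ml/min^alpha (>= 0).
#' @param alpha Shape parameter (> 0); the continuous curve peaks at
#'   `alpha * beta` minutes.
#' @param beta Decay time constant in minutes (> 0).
#' @param region Region label.
#' @return A [tac()] with attribute `ref_params`.
#' @export
simulate_reference_tac <- function(schedule, amplitude = 20, alpha = 2,
                                   beta = 1.2, region = "reference") {
  stopifnot(inherits(schedule, "frame_schedule"),
            amplitude >= 0, alpha > 0, beta > 0)
  fine <- fine_grid(schedule)
  cr <- amplitude * fine$t_min^alpha * exp(-fine$t_min / beta)
  out <- tac(schedule, frame_average(cr, fine), region)
  attr(out, "ref_params") <- list(amplitude = amplitude, alpha = alpha,
                                  beta = beta)
  out
}

# Reference curve on the fine grid: exact gamma variate if the TAC carries
# its parameters, else linear interpolation through (0, 0) and the frame
# midpoints.
fine_reference <- function(ref, fine) {
  p <- attr(ref, "ref_params")
  if (!is.null(p)) {
    p$amplitude * fine$t_min^p$alpha * exp(-fine$t_min / p$beta)
  } else {
    stats::approx(c(0, ref$schedule$mid / 60), c(0, ref$values),
                  xout = fine$t_min, rule = 2)$y
  }
}

#' Simulate a target-region TAC with the simplified reference tissue model
#'
#' Forward model for a reversibly binding tracer:
#' \deqn{C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_{2a})
#'   \left[C_R \otimes e^{-k_{2a} t}\right](t), \quad
#'   k_{2a} = k_2 / (1 + \mathrm{BP_{ND}})}
#' computed on a 1 s grid and frame-averaged. This is the simulator used to
#' generate targets with known binding potential for validating the Logan
#' graphical analysis; the package never fits this model.
#'
#' @param ref Reference-region [tac()] (ideally from
#'   [simulate_reference_tac()], whose exact continuous curve is then used).
#' @param r1 Relative delivery R1 (> 0).
#' @param k2 Reference efflux rate constant, 1/min (> 0).
#' @param bp_nd Non-displaceable binding potential (>= 0).
#' @param region Region label.
#' @return A target-region [tac()].
#' @export
simulate_srtm_tac <- function(ref, r1, k2, bp_nd, region = "target") {
  stopifnot(inherits(ref, "tac"), r1 > 0, k2 > 0, bp_nd >= 0)
  fine <- fine_grid(ref$schedule)
  cr <- fine_reference(ref, fine)
  k2a <- k2 / (1 + bp_nd)
  decay <- exp(-k2a * (seq_along(cr) - 1) * fine$dt_min)
  conv <- stats::convolve(cr, rev(decay), type = "open")[seq_along(cr)] *
    fine$dt_min
  ct <- r1 * cr + (k2 - r1 * k2a) * conv
  tac(ref$schedule, frame_average(ct, fine), region)
}

#' Render a dynamic image from region masks and TACs
#'
#' Builds a 4-D image in which each frame is piecewise constant over the
#' region masks (voxels outside all masks are 0), optionally with
#' count-dependent noise added independently per frame. An end-to-end
#' fixture generator for TAC-extraction tests.
#'
#' @param masks List of [roi_mask()] objects; must be pairwise disjoint.
#' @param tacs List of [tac()] objects, one per mask, sharing a schedule.
#' @param grid A [build_grid()] spec matching the masks.
#' @param schedule A [frame_schedule()].
#' @param noise Optional [noise_model()]; its seed determines the whole
#'   4-D realization.
#' @return An [image4d()].
#' @export
render_dynamic_image <- function(masks, tacs, grid, schedule, noise = NULL) {
  stopifnot(inherits(grid, "grid_spec"), inherits(schedule, "frame_schedule"))
  if (length(masks) != length(tacs))
    stop("invalid spec: need exactly one TAC per mask")
  if (!all(vapply(masks, inherits, TRUE, "roi_mask")))
    stop("'masks' must be roi_mask objects")
  if (!all(vapply(tacs, inherits, TRUE, "tac")))
    stop("'tacs' must be tac objects")
  all_idx <- unlist(lapply(masks, function(m) m$idx))
  if (anyDuplicated(all_idx))
    stop("invalid spec: masks overlap")
  nvox <- prod(grid$matrix)
  nframes <- nrow(schedule)
  values <- array(0, dim = c(grid$matrix, nframes))
  for (f in seq_len(nframes)) {
    frame <- numeric(nvox)
    for (i in seq_along(masks))
      frame[masks[[i]]$idx] <- tacs[[i]]$values[f]
    values[, , , f] <- frame
  }
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(noise$seed)
    values <- values + stats::rnorm(length(values)) * noise_sd(values, noise)
    values <- array(values, dim = c(grid$matrix, nframes))
  }
  image4d(values, grid, schedule)
}
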