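#' Extract regional TACs from a dynamic image
#'
#' Per-frame mean over each region's voxels.
#'
#' @param img4d An [image4d()].
#' @param label_masks Named list of [roi_mask()] objects.
#' @return Named list of [tac()] objects (one per region).
#' @export
extract_tacs <- function(img4d, label_masks) {
  stopifnot(inherits(img4d, "image4d"))
  if (!length(label_masks)) stop("no regions supplied")
  if (is.null(names(label_masks)))
    names(label_masks) <- paste0("region", seq_along(label_masks))
  nvox <- prod(img4d$grid$matrix)
  nframes <- nrow(img4d$schedule)
  flat <- img4d$values
  dim(flat) <- c(nvox, nframes)
  out <- lapply(names(label_masks), function(nm) {
    m <- label_masks[[nm]]
    if (!inherits(m, "roi_mask") || !length(m$idx))
      stop("empty or invalid region: ", nm)
    tac(img4d$schedule, colMeans(flat[m$idx, , drop = FALSE]), region = nm)
  })
  names(out) <- names(label_masks)
  out
}

#' Cumulative integral of a frame-average TAC
#'
#' Piecewise-constant integration (exact for frame-average data): the
#' integral to time `t` is the sum of value x duration over completed
#' frames plus the partial contribution of the frame containing `t`.
#'
#' @param tac A [tac()].
#' @param t Time(s) in seconds, `0 <= t <=` total duration.
#' @return Integral(s) in kBq s/ml.
#' @export
cumulative_integral <- function(tac, t) {
  stopifnot(inherits(tac, "tac"))
  if (any(t < 0)) stop("t must be >= 0")
  ends <- tac$schedule$start + tac$schedule$duration
  t_total <- max(ends)
  if (any(t > t_total + 1e-9)) stop("t exceeds the acquisition duration")
  cum_ends <- cumsum(tac$values * tac$schedule$duration)
  vapply(t, function(ti) {
    done <- ends <= ti + 1e-12
    base <- if (any(done)) cum_ends[max(which(done))] else 0
    f <- which(!done)[1L]
    if (is.na(f)) return(base)
    partial <- max(0, ti - tac$schedule$start[f])
    base + tac$values[f] * partial
  }, 0)
}

#' Reference-region Logan graphical analysis
#'
#' Estimates the distribution volume ratio (DVR) and the non-displaceable
#' binding potential BP_ND = DVR - 1 by ordinary least squares on the
#' linearized late-time plot
#' \deqn{\frac{\int_0^{t_i} C_T}{C_T(t_i)} = \mathrm{DVR} \cdot
#'   \frac{\int_0^{t_i} C_R + C_R(t_i)/k_2'}{C_T(t_i)} + b}
#' over frames whose mid-time is at or beyond `t_star`. The reference
#' efflux term `C_R/k2_ref` is omitted by default (late `t_star` makes its
#' influence small); supply `k2_ref` (1/min) to include it. No
#' errors-in-variables correction is applied, so noise-induced
#' underestimation at low signal-to-noise is expected and documented rather
#' than corrected.
#'
#' @param target Target-region [tac()].
#' @param reference Reference-region [tac()] on the same schedule.
#' @param t_star Start of the linear window in minutes (default 20).
#' @param k2_ref Optional reference-region efflux rate constant, 1/min.
#' @return An object of class `logan_fit`: `dvr`, `bp_nd` (= dvr - 1),
#'   `intercept`, `t_star`, `k2_ref`, `n_points_used`, `r_squared`,
#'   `max_rel_residual` (largest relative deviation of Y from the fitted
#'   line, a linearity diagnostic for choosing `t_star`).
#' @export
logan_bpnd <- function(target, reference, t_star = 20, k2_ref = NULL) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (nrow(target$schedule) != nrow(reference$schedule))
    stop("target and reference schedules differ")
  mids_min <- target$schedule$mid / 60
  sel <- which(mids_min >= t_star)
  if (length(sel) < 3L)
    stop("insufficient points: need >= 3 frames with mid-time >= t_star")
  ct <- target$values[sel]
  if (any(ct <= 0))
    stop("non-positive target values in the Logan window")
  mid_s <- target$schedule$mid[sel]
  int_t <- cumulative_integral(target, mid_s) / 60
  int_r <- cumulative_integral(reference, mid_s) / 60
  y <- int_t / ct
  x <- int_r / ct
  if (!is.null(k2_ref)) {
    stopifnot(is.finite(k2_ref), k2_ref > 0)
    x <- x + reference$values[sel] / (k2_ref * ct)
  }
  vx <- stats::var(x)
  if (vx <= 0) stop("degenerate Logan plot: abscissa has zero variance")
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    dvr = slope, bp_nd = slope - 1,
    intercept = intercept,
    t_star = t_star, k2_ref = k2_ref,
    n_points_used = length(sel),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    max_rel_residual = max(abs(y - yhat) / pmax(abs(yhat),
                                                .Machine$double.eps))),
    class = "logan_fit")
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf(
    "logan_fit: DVR = %.4g, BP_ND = %.4g (t* = %g min, %d points, R2 = %.5f)\n",
    x$dvr, x$bp_nd, x$t_star, x$n_points_used, x$r_squared))
  invisible(x)
}

#' Late-window activity ratio
#'
#' Target-to-reference ratio of duration-weighted mean concentrations over
#' the frames whose mid-times fall in the final `window_minutes` of the
#' acquisition (the conventional late-scan ratio for FDG with the pons as
#' reference).
#'
#' @param target Target-region [tac()].
#' @param reference Reference-region [tac()] on the same schedule.
#' @param window_minutes Length of the final window in minutes (default 30).
#' @return An object of class `ratio_result`: `target`, `reference`,
#'   `window` (start/end, min), `n_frames`, `ratio`.
#' @export
ratio_last_window <- function(target, reference, window_minutes = 30) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (nrow(target$schedule) != nrow(reference$schedule))
    stop("target and reference schedules differ")
  t_total <- total_duration(target$schedule)
  if (window_minutes > t_total + 1e-9)
    stop("window exceeds the acquisition duration")
  w_start <- t_total - window_minutes
  sel <- which(target$schedule$mid / 60 >= w_start)
  if (!length(sel)) stop("no frames in the final window")
  dur <- target$schedule$duration[sel]
  mean_t <- sum(target$values[sel] * dur) / sum(dur)
  mean_r <- sum(reference$values[sel] * dur) / sum(dur)
  if (mean_r <= 0) stop("reference mean in the window must be > 0")
  structure(list(target = target$region, reference = reference$region,
                 window = c(start = w_start, end = t_total),
                 n_frames = length(sel), ratio = mean_t / mean_r),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("ratio_result: %s / %s = %.4g (last %g-%g min, %d frames)\n",
              x$target, x$reference, x$ratio, x$window[1L], x$window[2L],
              x$n_frames))
  invisible(x)
}
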