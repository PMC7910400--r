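fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Separable 1-D convolution along one array axis with zero padding. The
# kernel is normalized to unit sum, so total activity is conserved exactly
# for signal further than the kernel half-width from the array boundary.
conv_axis <- function(a, w, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- d[axis]
  m <- prod(d[-axis])
  dim(ap) <- c(n, m)
  h <- (length(w) - 1L) %/% 2L
  pad <- matrix(0, n + 2L * h, m)
  pad[(h + 1L):(h + n), ] <- ap
  out <- matrix(0, n, m)
  for (k in seq_along(w))
    out <- out + w[k] * pad[k:(k + n - 1L), , drop = FALSE]
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

#' Blur an image with an isotropic Gaussian point spread function
#'
#' Emulates scanner resolution (and/or Gaussian post-filtering) by
#' convolving the image with an isotropic Gaussian of the given FWHM in
#' world (mm) units. The convolution is separable, uses a zero-padded
#' boundary (the phantom is surrounded by air) and a kernel truncated at
#' four standard deviations and renormalized to unit sum, so total activity
#' of an interior object is conserved to numerical precision.
#'
#' @param img An [image3d()].
#' @param fwhm Full width at half maximum of the Gaussian in mm (>= 0);
#'   `fwhm = 0` returns the image unchanged.
#' @return A blurred [image3d()].
#' @export
apply_psf <- function(img, fwhm) {
  stopifnot(inherits(img, "image3d"))
  if (!is.finite(fwhm) || fwhm < 0)
    stop("invalid PSF spec: fwhm must be >= 0")
  if (fwhm == 0) return(img)
  sigma <- fwhm_to_sigma(fwhm)
  values <- img$values
  for (axis in 1:3) {
    vox <- img$grid$voxel_size[axis]
    h <- max(1L, as.integer(ceiling(4 * sigma / vox)))
    w <- stats::dnorm((-h:h) * vox, sd = sigma)
    values <- conv_axis(values, w / sum(w), axis)
  }
  image3d(values, img$grid)
}

#' Radial profile of a Gaussian-blurred uniform sphere
#'
#' Closed form for the value at distance `r` from the centre of a uniform
#' unit-amplitude sphere of radius `R` convolved with an isotropic Gaussian
#' of standard deviation `sigma`:
#' \deqn{f(r) = \tfrac12\left[\mathrm{erf}\!\left(\tfrac{R-r}{\sigma\sqrt2}\right)
#'   + \mathrm{erf}\!\left(\tfrac{R+r}{\sigma\sqrt2}\right)\right]
#'   - \frac{\sigma}{r\sqrt{2\pi}}\left[e^{-(R-r)^2/2\sigma^2}
#'   - e^{-(R+r)^2/2\sigma^2}\right]}
#' with the \eqn{r \to 0} limit
#' \eqn{\mathrm{erf}(R/\sigma\sqrt2) - \sqrt{2/\pi}(R/\sigma)e^{-R^2/2\sigma^2}}.
#' This is the independent oracle for partial-volume loss used to validate
#' the rasterize-and-blur pipeline; it is itself validated once against
#' direct numerical 3-D convolution in the test suite.
#'
#' @param r Distance(s) from the sphere centre, mm.
#' @param radius Sphere radius, mm (> 0).
#' @param sigma Gaussian standard deviation, mm (>= 0). `sigma = 0` returns
#'   the sharp indicator (value 0.5 exactly on the surface).
#' @return Blurred fraction(s) in `[0, 1]`.
#' @export
blurred_sphere_profile <- function(r, radius, sigma) {
  stopifnot(radius > 0, sigma >= 0)
  r <- abs(r)
  if (sigma == 0) return(ifelse(r < radius, 1, ifelse(r == radius, 0.5, 0)))
  s2 <- sigma * sqrt(2)
  out <- numeric(length(r))
  small <- r < 1e-9 * radius
  if (any(small)) {
    out[small] <- erf(radius / s2) -
      sqrt(2 / pi) * (radius / sigma) * exp(-radius^2 / (2 * sigma^2))
  }
  rr <- r[!small]
  if (length(rr)) {
    out[!small] <- 0.5 * (erf((radius - rr) / s2) + erf((radius + rr) / s2)) -
      sigma / (rr * sqrt(2 * pi)) *
        (exp(-(radius - rr)^2 / (2 * sigma^2)) -
           exp(-(radius + rr)^2 / (2 * sigma^2)))
  }
  out
}

#' Centre value of a Gaussian-blurred uniform sphere
#'
#' Value at the centre of a uniform sphere of amplitude
#' `contrast_amplitude` after isotropic Gaussian blurring: the analytic
#' partial-volume oracle
#' \eqn{A\,[\mathrm{erf}(R/\sigma\sqrt2) - \sqrt{2/\pi}(R/\sigma)
#' e^{-R^2/2\sigma^2}]}.
#'
#' @param radius Sphere radius, mm (> 0).
#' @param contrast_amplitude Sphere amplitude above its surround, kBq/ml.
#' @param sigma Gaussian standard deviation, mm (>= 0); `sigma = 0` returns
#'   the amplitude exactly.
#' @return Blurred centre value, kBq/ml.
#' @export
analytic_center_value <- function(radius, contrast_amplitude, sigma) {
  if (!is.finite(radius) || radius <= 0) stop("'radius' must be > 0")
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) return(contrast_amplitude)
  contrast_amplitude * blurred_sphere_profile(0, radius, sigma)
}

#' Analytic blurred-phantom value at world points
#'
#' Independent prediction of the noiseless blurred phantom image at
#' arbitrary world points, built from closed forms: each sphere contributes
#' `(concentration - background) * blurred_sphere_profile()`, and the warm
#' cylinder contributes the background level attenuated by an erf edge
#' model in the radial and axial directions (curvature of the cylinder wall
#' is neglected, adequate when `sigma` is small relative to the cylinder
#' radius). Used as the oracle against which pipeline recovery coefficients
#' are checked.
#'
#' @param points n x 3 matrix of world mm coordinates.
#' @param phantom A [phantom_spec()].
#' @param fwhm Gaussian PSF FWHM in mm.
#' @return Numeric vector of predicted kBq/ml values at the points.
#' @export
analytic_phantom_values <- function(points, phantom, fwhm) {
  stopifnot(inherits(phantom, "phantom_spec"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  sigma <- fwhm_to_sigma(fwhm)
  rho <- sqrt(points[, 1L]^2 + points[, 2L]^2)
  if (sigma == 0) {
    f_cyl <- as.numeric(rho <= phantom$cylinder_radius &
                          abs(points[, 3L]) <= phantom$cylinder_height / 2)
  } else {
    f_cyl <- stats::pnorm((phantom$cylinder_radius - rho) / sigma) *
      stats::pnorm((phantom$cylinder_height / 2 - points[, 3L]) / sigma) *
      stats::pnorm((phantom$cylinder_height / 2 + points[, 3L]) / sigma)
  }
  vals <- phantom$background_concentration * f_cyl
  for (s in phantom$spheres) {
    r <- sqrt((points[, 1L] - s$center[1L])^2 +
                (points[, 2L] - s$center[2L])^2 +
                (points[, 3L] - s$center[3L])^2)
    vals <- vals + (s$concentration - phantom$background_concentration) *
      blurred_sphere_profile(r, s$inner_diameter / 2, sigma)
  }
  vals
}

#' Analytic mean of the blurred phantom over a mask
#'
#' Predicts the mean voxel value a measurement ROI would see on a blurred
#' phantom image, entirely from closed forms: [analytic_phantom_values()]
#' averaged over each mask voxel with `subsample^3` sub-voxel points (the
#' image voxel holds a voxel average, so the prediction must too). This is
#' the independent oracle for the rasterize-convolve-measure pipeline and
#' shares none of its code path.
#'
#' @param mask A [roi_mask()].
#' @param grid The [build_grid()] spec the mask indexes.
#' @param phantom A [phantom_spec()].
#' @param fwhm Gaussian PSF FWHM in mm.
#' @param subsample Per-axis sub-voxel sampling of the closed form.
#' @return Predicted mean value in kBq/ml.
#' @export
analytic_roi_mean <- function(mask, grid, phantom, fwhm, subsample = 3L) {
  stopifnot(inherits(mask, "roi_mask"), inherits(grid, "grid_spec"))
  ijk <- arrayInd(mask$idx, grid$matrix)
  pts <- cbind(grid_axis_coords(grid, 1L)[ijk[, 1L]],
               grid_axis_coords(grid, 2L)[ijk[, 2L]],
               grid_axis_coords(grid, 3L)[ijk[, 3L]])
  off <- subsample_offsets(subsample, grid$voxel_size)
  sub <- expand.grid(dx = off$x, dy = off$y, dz = off$z)
  acc <- 0
  for (q in seq_len(nrow(sub)))
    acc <- acc + analytic_phantom_values(
      sweep(pts, 2L, as.numeric(sub[q, ]), "+"), phantom, fwhm)
  mean(acc / nrow(sub))
}
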