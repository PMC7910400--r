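#' Sphere specification
#'
#' A fillable sphere of the contrast phantom: position, inner diameter and
#' true activity concentration (0 for water-filled cold spheres).
#'
#' @param center World mm triple of the sphere centre.
#' @param inner_diameter Inner diameter in mm.
#' @param concentration True activity concentration in kBq/ml (>= 0).
#' @return An object of class `sphere_spec`.
#' @export
sphere_spec <- function(center, inner_diameter, concentration) {
  if (length(center) != 3L || !all(is.finite(center)))
    stop("sphere center must be a finite mm triple")
  if (!is.finite(inner_diameter) || inner_diameter <= 0)
    stop("sphere inner_diameter must be > 0")
  if (!is.finite(concentration) || concentration < 0)
    stop("sphere concentration must be >= 0")
  structure(list(center = as.numeric(center),
                 inner_diameter = inner_diameter,
                 concentration = concentration),
            class = "sphere_spec")
}

#' Phantom specification
#'
#' A warm cylinder ("contrast phantom") containing fillable spheres. The
#' cylinder axis is the z (axial) axis through the world origin. The derived
#' `contrast_ratio` is the hot-sphere to background concentration ratio and
#' must be consistent with the stated concentrations.
#'
#' @param cylinder_radius Interior radius in mm.
#' @param cylinder_height Interior height in mm (centred on z = 0).
#' @param background_concentration Background concentration in kBq/ml.
#' @param spheres List of [sphere_spec()] objects.
#' @return An object of class `phantom_spec`; `$contrast_ratio` holds the
#'   hot-to-background ratio (NA if there is no hot sphere).
#' @export
phantom_spec <- function(cylinder_radius, cylinder_height,
                         background_concentration, spheres) {
  stopifnot(is.finite(cylinder_radius), cylinder_radius > 0,
            is.finite(cylinder_height), cylinder_height > 0,
            is.finite(background_concentration), background_concentration > 0)
  if (!length(spheres) || !all(vapply(spheres, inherits, TRUE, "sphere_spec")))
    stop("'spheres' must be a non-empty list of sphere_spec objects")
  for (s in spheres) {
    r <- s$inner_diameter / 2
    if (sqrt(sum(s$center[1:2]^2)) + r > cylinder_radius + 1e-9 ||
        abs(s$center[3]) + r > cylinder_height / 2 + 1e-9)
      stop(sprintf("sphere (d = %.3g mm) does not fit inside the cylinder",
                   s$inner_diameter))
  }
  hot <- vapply(spheres, function(s) s$concentration, 0)
  hot <- hot[hot > 0]
  contrast_ratio <- if (length(hot)) {
    cr <- hot / background_concentration
    if (diff(range(cr)) > 1e-9 * mean(cr))
      stop("hot spheres have inconsistent contrast ratios")
    cr[1L]
  } else NA_real_
  structure(list(cylinder_radius = cylinder_radius,
                 cylinder_height = cylinder_height,
                 background_concentration = background_concentration,
                 spheres = spheres, contrast_ratio = contrast_ratio),
            class = "phantom_spec")
}

#' Default digital contrast phantom
#'
#' A warm 6-litre-class cylinder with six spheres of inner diameters 9.9,
#' 12.4, 15.4, 19.8, 24.8 and 31.3 mm on a ring in the central transaxial
#' plane. The four smallest spheres are hot at `contrast`:1 relative to the
#' background; the two largest are water-filled (cold).
#'
#' @param background_concentration Background concentration, kBq/ml.
#' @param contrast Hot-sphere to background concentration ratio.
#' @param ring_radius Radius (mm) of the circle of sphere centres.
#' @param cylinder_radius,cylinder_height Cylinder interior dimensions, mm.
#' @return A `phantom_spec`.
#' @export
contrast_phantom <- function(background_concentration = 4.8, contrast = 3.88,
                             ring_radius = 35, cylinder_radius = 108,
                             cylinder_height = 186) {
  diameters <- c(9.9, 12.4, 15.4, 19.8, 24.8, 31.3)
  conc <- c(rep(contrast * background_concentration, 4L), 0, 0)
  ang <- (seq_along(diameters) - 1) * pi / 3
  spheres <- Map(function(d, c_, a)
    sphere_spec(c(ring_radius * cos(a), ring_radius * sin(a), 0), d, c_),
    diameters, conc, ang)
  phantom_spec(cylinder_radius, cylinder_height, background_concentration,
               spheres)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: cylinder r = %.4g mm, h = %.4g mm, bg = %.4g kBq/ml\n",
    x$cylinder_radius, x$cylinder_height, x$background_concentration))
  for (s in x$spheres)
    cat(sprintf("  sphere d = %.3g mm at (%.3g, %.3g, %.3g), %.4g kBq/ml\n",
                s$inner_diameter, s$center[1], s$center[2], s$center[3],
                s$concentration))
  invisible(x)
}

# Sub-voxel offsets for partial-volume-aware rasterization: s points per
# axis at the centres of an s x s x s subdivision of the voxel.
subsample_offsets <- function(subsample, voxel) {
  u <- ((seq_len(subsample) - 0.5) / subsample - 0.5)
  list(x = u * voxel[1L], y = u * voxel[2L], z = u * voxel[3L])
}

#' Rasterize a phantom onto a voxel grid
#'
#' Produces a noiseless, unblurred digital image of the phantom. Voxels cut
#' by a sphere or the cylinder surface receive a volume-fraction-weighted
#' mixture of the adjoining concentrations, estimated by `subsample^3`
#' sub-voxel points (edge voxels only; interior voxels are exact). Voxels
#' outside the cylinder are 0.
#'
#' @param phantom A [phantom_spec()].
#' @param grid A [build_grid()] spec.
#' @param subsample Per-axis sub-voxel sampling factor (>= 1).
#' @return An [image3d()] in kBq/ml.
#' @export
rasterize_phantom <- function(phantom, grid, subsample = 4L) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(grid, "grid_spec"))
  subsample <- as.integer(subsample)
  if (is.na(subsample) || subsample < 1L) stop("'subsample' must be >= 1")

  nx <- grid$matrix[1L]; ny <- grid$matrix[2L]; nz <- grid$matrix[3L]
  vx <- grid$voxel_size
  xs <- grid_axis_coords(grid, 1L)
  ys <- grid_axis_coords(grid, 2L)
  zs <- grid_axis_coords(grid, 3L)
  off <- subsample_offsets(subsample, vx)

  # Cylinder coverage separates into an in-plane disc fraction and an axial
  # interval-overlap fraction (exact).
  half_diag_xy <- sqrt(vx[1L]^2 + vx[2L]^2) / 2
  rho <- sqrt(outer(xs^2, ys^2, "+"))
  f_xy <- matrix(0, nx, ny)
  f_xy[rho <= phantom$cylinder_radius - half_diag_xy] <- 1
  edge <- which(abs(rho - phantom$cylinder_radius) < half_diag_xy,
                arr.ind = TRUE)
  if (nrow(edge)) {
    sub2 <- expand.grid(dx = off$x, dy = off$y)
    for (r in seq_len(nrow(edge))) {
      px <- xs[edge[r, 1L]] + sub2$dx
      py <- ys[edge[r, 2L]] + sub2$dy
      f_xy[edge[r, 1L], edge[r, 2L]] <-
        mean(px^2 + py^2 <= phantom$cylinder_radius^2)
    }
  }
  zh <- phantom$cylinder_height / 2
  f_z <- pmax(0, (pmin(zs + vx[3L] / 2, zh) - pmax(zs - vx[3L] / 2, -zh))) /
    vx[3L]
  f_cyl <- array(outer(f_xy, f_z), dim = c(nx, ny, nz))

  sub3 <- expand.grid(dx = off$x, dy = off$y, dz = off$z)
  half_diag <- sqrt(sum(vx^2)) / 2
  f_sph_total <- array(0, dim = c(nx, ny, nz))
  values <- phantom$background_concentration * f_cyl

  for (s in phantom$spheres) {
    r_s <- s$inner_diameter / 2
    lo <- s$center - r_s - half_diag
    hi <- s$center + r_s + half_diag
    ilo <- pmax(1L, ceiling((lo - grid$origin) / vx) + 1L)
    ihi <- pmin(grid$matrix, floor((hi - grid$origin) / vx) + 1L)
    if (any((lo - grid$origin) / vx + 1 < 0.5) ||
        any((hi - grid$origin) / vx + 1 > grid$matrix + 0.5))
      warning(sprintf("sphere (d = %.3g mm) extends outside the grid; clipped",
                      s$inner_diameter))
    if (any(ilo > ihi)) next
    ii <- ilo[1L]:ihi[1L]; jj <- ilo[2L]:ihi[2L]; kk <- ilo[3L]:ihi[3L]
    dx2 <- (xs[ii] - s$center[1L])^2
    dy2 <- (ys[jj] - s$center[2L])^2
    dz2 <- (zs[kk] - s$center[3L])^2
    dist <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    frac <- array(0, dim = dim(dist))
    frac[dist <= r_s - half_diag] <- 1
    shell <- which(abs(dist - r_s) < half_diag, arr.ind = TRUE)
    if (nrow(shell)) {
      for (q in seq_len(nrow(shell))) {
        cx <- xs[ii[shell[q, 1L]]]; cy <- ys[jj[shell[q, 2L]]]
        cz <- zs[kk[shell[q, 3L]]]
        d2 <- (cx + sub3$dx - s$center[1L])^2 +
          (cy + sub3$dy - s$center[2L])^2 +
          (cz + sub3$dz - s$center[3L])^2
        frac[shell[q, 1L], shell[q, 2L], shell[q, 3L]] <- mean(d2 <= r_s^2)
      }
    }
    f_sph_total[ii, jj, kk] <- f_sph_total[ii, jj, kk] + frac
    values[ii, jj, kk] <- values[ii, jj, kk] +
      (s$concentration - phantom$background_concentration) * frac
  }
  # Guard against tiny negative residuals where sphere and cylinder edge
  # fractions disagree at float precision.
  values[values < 0 & values > -1e-9] <- 0
  image3d(values, grid)
}

#' Analytic total activity of a phantom
#'
#' Closed-form total activity (kBq): cylinder volume times background
#' concentration, with each sphere's volume swapped from background to its
#' own concentration. Used as an independent check on rasterization.
#'
#' @param phantom A [phantom_spec()].
#' @return Total activity in kBq.
#' @export
phantom_total_activity <- function(phantom) {
  v_cyl <- pi * phantom$cylinder_radius^2 * phantom$cylinder_height / 1000
  total <- v_cyl * phantom$background_concentration
  for (s in phantom$spheres) {
    v_s <- pi / 6 * s$inner_diameter^3 / 1000
    total <- total + v_s * (s$concentration - phantom$background_concentration)
  }
  total
}
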