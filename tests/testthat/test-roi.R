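# Independent brute-force point-in-shape oracles.
brute_circle_count <- function(center, diameter, grid, slice) {
  xs <- grid_axis_coords(grid, 1)
  ys <- grid_axis_coords(grid, 2)
  n <- 0L
  for (i in seq_along(xs)) for (j in seq_along(ys))
    if ((xs[i] - center[1])^2 + (ys[j] - center[2])^2 <= (diameter / 2)^2)
      n <- n + 1L
  n
}

brute_sphere_indices <- function(center, diameter, grid) {
  xs <- grid_axis_coords(grid, 1)
  ys <- grid_axis_coords(grid, 2)
  zs <- grid_axis_coords(grid, 3)
  idx <- integer()
  for (k in seq_along(zs)) for (j in seq_along(ys)) for (i in seq_along(xs))
    if ((xs[i] - center[1])^2 + (ys[j] - center[2])^2 +
        (zs[k] - center[3])^2 <= (diameter / 2)^2)
      idx <- c(idx, i + (j - 1L) * grid$matrix[1] +
                 (k - 1L) * grid$matrix[1] * grid$matrix[2])
  sort(idx)
}

test_that("circular ROI rasterization matches a brute-force scan", {
  g <- build_grid(c(40L, 40L, 10L), 48.8, 1.22)  # 1.22 mm voxels
  roi <- circular_roi(c(1.7, -2.3), 9.9, slice_index = 5L)
  m <- rasterize_circular_roi(roi, g)
  expect_equal(m$voxel_count,
               brute_circle_count(c(1.7, -2.3), 9.9, g, 5L))
  # all mask voxels live on the requested slice
  k <- (m$idx - 1L) %/% (40L * 40L) + 1L
  expect_true(all(k == 5L))
})

test_that("degenerate and translated circular ROIs behave on the lattice", {
  g <- build_grid(c(20L, 20L, 4L), 40, 2)
  centre_vox <- grid_axis_coords(g, 1)[10]
  tiny <- circular_roi(c(centre_vox, centre_vox), 1.5, 2L)
  expect_equal(rasterize_circular_roi(tiny, g)$voxel_count, 1L)
  # translation by one full voxel pitch preserves the count
  a <- circular_roi(c(1.3, 0.2), 9.9, 2L)
  b <- circular_roi(c(1.3 + 2, 0.2 - 2), 9.9, 2L)
  expect_equal(rasterize_circular_roi(a, g)$voxel_count,
               rasterize_circular_roi(b, g)$voxel_count)
})

test_that("spherical VOI rasterization matches brute force and volume", {
  g <- build_grid(c(40L, 40L, 32L), 48.8, 1.22)
  voi <- spherical_voi(c(0.3, -0.7, 0.2), 31.3 / 2)  # keep inside small grid
  m <- rasterize_spherical_voi(voi, g)
  expect_identical(m$idx, brute_sphere_indices(voi$center, voi$diameter, g))

  big <- spherical_voi(c(0, 0, 0), 31.3)
  g2 <- build_grid(c(40L, 40L, 32L), 48.8, 1.22)
  m2 <- rasterize_spherical_voi(big, g2)
  expected <- (pi / 6) * 31.3^3 / prod(g2$voxel_size)
  expect_equal(m2$voxel_count, expected, tolerance = 0.02)

  tiny <- spherical_voi(c(grid_axis_coords(g, 1)[20],
                          grid_axis_coords(g, 2)[20],
                          grid_axis_coords(g, 3)[16]), 0.9)
  expect_equal(rasterize_spherical_voi(tiny, g)$voxel_count, 1L)
})

test_that("most visible slice is found for hot and cold spheres", {
  ph <- contrast_phantom()
  g <- build_grid(c(96L, 96L, 61L), 292.8, 3)
  img <- apply_psf(rasterize_phantom(ph, g, subsample = 2), 4)
  centre_slice <- which.min(abs(grid_axis_coords(g, 3)))
  hot <- ph$spheres[[4]]
  cold <- ph$spheres[[6]]
  expect_equal(find_most_visible_slice(img, hot, "hot"), centre_slice)
  expect_equal(find_most_visible_slice(img, cold, "cold"), centre_slice)
  # boosting the centre slice keeps it on top
  boosted <- img
  boosted$values[, , centre_slice] <- boosted$values[, , centre_slice] * 1.10
  expect_equal(find_most_visible_slice(boosted, hot, "hot"), centre_slice)
  # boosting a neighbouring slice enough makes it win
  boosted2 <- img
  boosted2$values[, , centre_slice + 1] <-
    boosted2$values[, , centre_slice + 1] * 1.5
  expect_equal(find_most_visible_slice(boosted2, hot, "hot"),
               centre_slice + 1)
  # sphere far outside the image errors
  far <- sphere_spec(c(0, 0, 500), 10, 1)
  expect_error(find_most_visible_slice(img, far, "hot"), "outside")
})

test_that("background grid yields exactly 60 disjoint in-cylinder ROIs per size", {
  ph <- contrast_phantom()
  g <- build_grid(c(128L, 128L, 89L), 356, 2.78)
  central <- which.min(abs(grid_axis_coords(g, 3)))
  bg <- build_background_grid(ph, g, central)
  expect_equal(length(bg$rois), 6L)
  for (set in bg$rois) expect_equal(length(set), 60L)
  # background masks are disjoint from every sphere mask
  sphere_masks <- lapply(ph$spheres, function(s)
    rasterize_spherical_voi(spherical_voi(s$center, s$inner_diameter), g))
  sphere_idx <- unlist(lapply(sphere_masks, function(m) m$idx))
  for (set in bg$rois) {
    bg_idx <- unlist(lapply(set, function(roi)
      rasterize_circular_roi(roi, g)$idx))
    expect_length(intersect(bg_idx, sphere_idx), 0)
  }
})

test_that("infeasible background layouts raise geometry errors", {
  ph <- contrast_phantom()
  g <- build_grid(c(128L, 128L, 89L), 356, 2.78)
  central <- which.min(abs(grid_axis_coords(g, 3)))
  # margin larger than the cylinder: nothing can be placed
  expect_error(build_background_grid(ph, g, central, margin = 200),
               "geometry error")
  # layout circle too small for 12 non-overlapping largest ROIs
  expect_error(build_background_grid(ph, g, central, layout_radius = 20),
               "layout_radius")
  # ROI ring through the sphere ring violates the margin
  expect_error(build_background_grid(ph, g, central, layout_radius = 35),
               "margin|sphere")
})

test_that("roi_set assembles sphere ROIs, VOIs and background per sphere", {
  fix <- study_phantom_image(subsample = 2L)
  img <- apply_psf(fix$img, 4.5)
  rois <- build_roi_set(img, fix$phantom)
  expect_length(rois$spheres, 6L)
  expect_equal(vapply(rois$spheres, function(s) s$polarity, ""),
               c(rep("hot", 4), rep("cold", 2)))
  expect_equal(length(rois$background$rois[["9.9"]]), 60L)
})
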