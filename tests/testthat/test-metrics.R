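test_that("hot recovery coefficient implements the contrast formula", {
  # perfect recovery: measured ratio equals true ratio
  expect_equal(rc_hot(3.88, 1, 3.88, 1), 100)
  # measured ratio 2.44 against true ratio 3.88 -> exactly 50%
  expect_equal(rc_hot(2.44, 1, 3.88, 1), 50)
  # no recovered contrast
  expect_equal(rc_hot(5, 5, 3.88, 1), 0)
  # overshoot above 100% is not clamped
  expect_gt(rc_hot(4.5, 1, 3.88, 1), 100)
  expect_error(rc_hot(1, 1, 2, 2), "undefined contrast")
  expect_error(rc_hot(1, 0, 3.88, 1), "c_background")
})

test_that("cold recovery coefficient implements the suppression formula", {
  expect_equal(rc_cold(0, 5), 100)
  expect_equal(rc_cold(5, 5), 0)
  expect_equal(rc_cold(1, 5), 80)
  expect_error(rc_cold(1, 0), "c_background")
})

test_that("background variability is the CoV of the ROI means", {
  expect_equal(bg_variability(c(9, 10, 11)), 10)
  expect_equal(bg_variability(rep(7, 60)), 0)
  # scale invariance
  x <- c(4.1, 4.4, 5.2, 4.9, 4.6)
  expect_equal(bg_variability(x), bg_variability(13 * x))
  expect_error(bg_variability(5), "at least 2")
})

test_that("voxel noise is the pooled within-ROI coefficient of variation", {
  g <- build_grid(c(10L, 10L, 1L), 20, 2)
  vals <- array(rep(c(8, 12), 50), dim = c(10, 10, 1))
  img <- image3d(vals, g)
  mask <- roi_mask(1:100, g)
  # sample SD of 50x{8,12} = 2.0100..., mean 10 -> 20.1%
  expect_equal(voxel_noise(mask, img), 20.1, tolerance = 1e-3)
  # constant image -> 0
  expect_equal(voxel_noise(mask, uniform_image(3, c(10L, 10L, 1L), 2)), 0)
  # adding a uniform offset lowers the percentage
  img2 <- image3d(vals + 5, g)
  expect_lt(voxel_noise(mask, img2), voxel_noise(mask, img))
  # scale invariance
  img3 <- image3d(vals * 3, g)
  expect_equal(voxel_noise(mask, img3), voxel_noise(mask, img))
})

test_that("voxel noise decreases under smoothing of a noisy uniform image", {
  # interior mask, clear of the zero-padded boundary
  img <- uniform_image(value = 10, n = c(32L, 32L, 32L), voxel = 2)
  noisy <- add_noise(img, noise_model(5e6, seed = 11))
  interior <- array(FALSE, dim = c(32, 32, 32))
  interior[10:23, 10:23, 10:23] <- TRUE
  mask <- roi_mask(which(interior), noisy$grid)
  raw <- voxel_noise(mask, noisy)
  smoothed <- voxel_noise(mask, apply_psf(noisy, 6))
  expect_lt(smoothed, raw / 2)
})

test_that("trajectories track metrics per iteration without smoothing", {
  fix <- study_phantom_image(subsample = 2L)
  blurred <- apply_psf(fix$img, 4.5)
  rois <- build_roi_set(blurred, fix$phantom)
  truth <- list(a_hot = 3.88 * 4.8, a_background = 4.8)
  # single image -> single iteration
  single <- rc_noise_trajectory(list(blurred), rois, truth)
  expect_equal(unique(single$iteration), 1)
  # identical images -> constant trajectory
  series <- list(blurred, blurred, blurred)
  traj <- rc_noise_trajectory(series, rois, truth)
  per_iter <- split(traj$rc_pct, traj$iteration)
  expect_equal(per_iter[[1]], per_iter[[2]])
  expect_equal(per_iter[[2]], per_iter[[3]])
  # growing noise -> strictly increasing voxel noise
  noisy_series <- lapply(c(40e6, 10e6, 2.5e6), function(p)
    add_noise(blurred, noise_model(p, seed = 5)))
  traj2 <- rc_noise_trajectory(noisy_series, rois, truth)
  vn <- vapply(split(traj2$voxel_noise_pct, traj2$iteration), mean, 0)
  expect_true(all(diff(vn) > 0))
})

test_that("line profiles sample at voxel pitch and normalize to activity", {
  img <- uniform_image(value = 8, n = c(24L, 24L, 12L), voxel = 2)
  prof <- line_profile(img, c(-20, 0, 0), c(20, 0, 0),
                       injected_activity = 4)
  expect_true(all(diff(prof$position_mm) > 0))
  expect_equal(unique(diff(prof$position_mm)), 2, tolerance = 1e-9)
  expect_equal(unique(prof$value), 8 / 4)
  # profile through a blurred sphere peaks at the centre sample
  ph <- single_sphere_phantom(diameter = 19.8)
  g <- small_grid()
  sph <- apply_psf(rasterize_phantom(ph, g, subsample = 2), 4)
  prof2 <- line_profile(sph, c(-30, 0, 0), c(30, 0, 0), 1)
  expect_equal(prof2$position_mm[which.max(prof2$value)], 30, tolerance = 2)
  expect_error(line_profile(img, c(0, 0, 0), c(0, 0, 0), 1), "zero-length")
  expect_error(line_profile(img, c(0, 0, 0), c(500, 0, 0), 1), "leaves")
})

test_that("sensitivity unit conversion reproduces both reporting conventions", {
  # plain cps/kBq -> percent conversion, printed as 2.3%
  expect_equal(round(sensitivity_percent(23.3, 70, 70), 1), 2.3)
  # renormalized to the 25 cm in-FOV portion of the 70 cm source: 6.5%
  expect_equal(round(sensitivity_percent(23.3, 70, 25), 1), 6.5)
  expect_equal(sensitivity_percent(0, 70, 25), 0)
})
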