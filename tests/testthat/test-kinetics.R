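test_that("TAC extraction has no cross-talk between disjoint regions", {
  g <- build_grid(c(10L, 10L, 4L), 20, 2)
  sch <- frame_schedule(rep(120, 3))
  ta <- tac(sch, c(5, 10, 2), "a")
  tb <- tac(sch, c(1, 0, 8), "b")
  img <- render_dynamic_image(list(roi_mask(1:30, g), roi_mask(51:90, g)),
                              list(ta, tb), g, sch)
  out <- extract_tacs(img, list(a = roi_mask(1:30, g),
                                b = roi_mask(51:90, g)))
  expect_equal(out$a$values, ta$values)
  expect_equal(out$b$values, tb$values)
  # constant image -> constant TAC
  cimg <- image4d(array(3, c(10, 10, 4, 3)), g, sch)
  expect_equal(extract_tacs(cimg, list(a = roi_mask(1:30, g)))$a$values,
               rep(3, 3))
})

test_that("cumulative integral is exact piecewise-constant quadrature", {
  sch <- frame_schedule(c(60, 120, 300))
  tc <- tac(sch, c(2, 4, 1))
  expect_equal(cumulative_integral(tc, 0), 0)
  # constant TAC: v * T
  const <- tac(sch, rep(3, 3))
  expect_equal(cumulative_integral(const, 480), 3 * 480)
  # frame boundaries are exact
  expect_equal(cumulative_integral(tc, 180), 2 * 60 + 4 * 120)
  # partial frame
  expect_equal(cumulative_integral(tc, 200), 2 * 60 + 4 * 120 + 1 * 20)
  expect_error(cumulative_integral(tc, -1), ">= 0")
  expect_error(cumulative_integral(tc, 1e5), "exceeds")
})

test_that("frame integration tracks a fine-grid trapezoid oracle on a ramp", {
  sch <- brain_pet_schedule("16-frame")
  slope_per_s <- 0.01
  fine_t <- seq(0, 3600, by = 0.5)
  ramp_fun <- function(t) slope_per_s * t
  frame_means <- slope_per_s * sch$mid  # exact frame averages of a ramp
  tc <- tac(sch, frame_means)
  for (t_eval in c(600, 1800, 3600)) {
    sel <- fine_t <= t_eval
    oracle <- sum(diff(fine_t[sel]) *
                    (ramp_fun(fine_t[sel])[-1] +
                       ramp_fun(fine_t[sel])[-sum(sel)]) / 2)
    expect_equal(cumulative_integral(tc, t_eval), oracle, tolerance = 0.02)
  }
})

test_that("Logan self-reference and pure scaling give exact DVRs", {
  ref <- simulate_reference_tac(brain_pet_schedule("16-frame"))
  fit <- logan_bpnd(ref, ref, t_star = 20)
  expect_equal(fit$dvr, 1, tolerance = 1e-12)
  expect_equal(fit$bp_nd, 0, tolerance = 1e-12)
  doubled <- tac(ref$schedule, 2 * ref$values, "x2")
  expect_equal(logan_bpnd(doubled, ref, t_star = 20)$dvr, 2,
               tolerance = 1e-12)
})

test_that("Logan recovers BP_ND across the SRTM parameter grid (noiseless)", {
  ref <- simulate_reference_tac(brain_pet_schedule("16-frame"))
  for (bp in c(0.5, 2, 4)) for (r1 in c(0.8, 1.2)) for (k2 in c(0.05, 0.15)) {
    tgt <- simulate_srtm_tac(ref, r1, k2, bp)
    fit <- logan_bpnd(tgt, ref, t_star = 20)
    expect_lt(abs(fit$bp_nd / bp - 1), 0.05)
    expect_equal(fit$bp_nd, fit$dvr - 1)
  }
})

test_that("Logan fit is invariant under joint scaling of both TACs", {
  ref <- simulate_reference_tac(brain_pet_schedule("16-frame"))
  tgt <- simulate_srtm_tac(ref, 1, 0.1, 2)
  f1 <- logan_bpnd(tgt, ref, t_star = 20)
  tgt2 <- tac(tgt$schedule, 37 * tgt$values)
  ref2 <- tac(ref$schedule, 37 * ref$values)
  f2 <- logan_bpnd(tgt2, ref2, t_star = 20)
  expect_equal(f1$dvr, f2$dvr, tolerance = 1e-12)
})

test_that("DVR moves monotonically toward 1 + bp_nd as t_star grows", {
  # slowly equilibrating configuration so the transient dominates
  sch <- brain_pet_schedule("16-frame")
  slow_ref <- simulate_reference_tac(sch, amplitude = 20, alpha = 0.25,
                                     beta = 24)
  tgt <- simulate_srtm_tac(slow_ref, 1, 0.1, 2)
  devs <- vapply(c(5, 10, 15, 20, 25), function(ts)
    abs(logan_bpnd(tgt, slow_ref, t_star = ts)$dvr - 3), 0)
  expect_true(all(diff(devs) < 0))
})

test_that("Logan preconditions are enforced", {
  ref <- simulate_reference_tac(brain_pet_schedule("16-frame"))
  expect_error(logan_bpnd(ref, ref, t_star = 55), "insufficient points")
  neg <- tac(ref$schedule, ref$values - max(ref$values), "neg")
  expect_error(logan_bpnd(neg, ref, t_star = 20), "non-positive")
  expect_error(logan_bpnd(simulate_srtm_tac(ref, 1, 0.1, 1), ref,
                          t_star = 20, k2_ref = -1), "k2_ref")
})

test_that("late-window ratio is the duration-weighted plateau ratio", {
  sch <- brain_pet_schedule("17-frame")
  ref <- simulate_reference_tac(sch, amplitude = 20, alpha = 0.6, beta = 80)
  same <- ratio_last_window(ref, ref)
  expect_equal(same$ratio, 1)
  scaled <- tac(sch, 1.5 * ref$values, "t")
  rr <- ratio_last_window(scaled, ref)
  expect_equal(rr$ratio, 1.5)
  # the 30-min window of the 17-frame schedule is exactly the last six
  # 300 s frames
  expect_equal(rr$n_frames, 6)
  expect_equal(rr$window, c(start = 30, end = 60))
  # constant-over-window TACs: ratio equals the plateau value ratio
  a <- tac(sch, c(seq(0, 5, length.out = 11), rep(8, 6)), "a")
  b <- tac(sch, c(seq(0, 9, length.out = 11), rep(2, 6)), "b")
  expect_equal(ratio_last_window(a, b)$ratio, 4)
  expect_error(ratio_last_window(a, b, window_minutes = 90), "exceeds")
})

test_that("Logan k2_ref term shifts the abscissa as specified", {
  ref <- simulate_reference_tac(brain_pet_schedule("16-frame"))
  tgt <- simulate_srtm_tac(ref, 1, 0.1, 2)
  with_term <- logan_bpnd(tgt, ref, t_star = 20, k2_ref = 0.1)
  without <- logan_bpnd(tgt, ref, t_star = 20)
  # the correction is small at late t_star but not zero
  expect_false(isTRUE(all.equal(with_term$dvr, without$dvr)))
  expect_lt(abs(with_term$bp_nd / 2 - 1), 0.05)
})
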