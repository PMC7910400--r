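test_that("scanner ratios, deviations and subject means are computed", {
  a <- scanner_record("A", c("caudate", "putamen"), c(2.0, 3.0))
  b <- scanner_record("B", c("caudate", "putamen"), c(2.0, 3.0))
  rep <- scanner_ratio(a, b)
  expect_equal(rep$regions$ratio, c(1, 1))
  expect_equal(rep$regions$deviation_pct, c(0, 0))

  b2 <- scanner_record("B", c("caudate", "putamen"), 2 * c(2.0, 3.0))
  rep2 <- scanner_ratio(a, b2)
  expect_equal(rep2$regions$ratio, c(0.5, 0.5))
  expect_equal(rep2$regions$deviation_pct, c(50, 50))

  # mean across subjects is the arithmetic mean of per-subject ratios
  a3 <- scanner_record("A", rep("caudate", 2), c(0.95, 1.05),
                       subject = c("s1", "s2"))
  b3 <- scanner_record("B", rep("caudate", 2), c(1, 1),
                       subject = c("s1", "s2"))
  rep3 <- scanner_ratio(a3, b3)
  expect_equal(rep3$tracer_means$mean_ratio, 1)
  expect_equal(rep3$tracer_means$n_subjects, 2)
})

test_that("ratios are element-wise reciprocal when records are swapped", {
  a <- scanner_record("A", c("r1", "r2", "r3"), c(1.2, 0.8, 2.5))
  b <- scanner_record("B", c("r1", "r2", "r3"), c(1.0, 1.1, 2.0))
  ab <- scanner_ratio(a, b)$regions$ratio
  ba <- scanner_ratio(b, a)$regions$ratio
  expect_equal(ab, 1 / ba)
})

test_that("missing regions are reported by name", {
  a <- scanner_record("A", c("caudate", "putamen"), c(2, 3))
  b <- scanner_record("B", "caudate", 2)
  expect_error(scanner_ratio(a, b), "putamen")
})

test_that("config validation names offending fields and requires a seed", {
  cfg <- demo_config(1)
  expect_silent(validate_config(cfg))
  no_seed <- cfg
  no_seed$seed <- NULL
  expect_error(validate_config(no_seed), "config\\$seed")
  bad <- cfg
  bad$scanners[[2]]$psf_fwhm <- -1
  expect_error(validate_config(bad), "scanners\\[\\[2\\]\\]\\$psf_fwhm")
  bad2 <- cfg
  bad2$kinetics$regions[[1]]$k2 <- NULL
  expect_error(validate_config(bad2), "regions\\[\\[1\\]\\]\\$k2")
})

test_that("pipeline runs are deterministic and self-contained", {
  cfg <- demo_config(3)
  # shrink the phantom stage to keep the double run fast
  cfg$phantom$low_count_replicates <- 2L
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfg, d1, write_images = FALSE)
  r2 <- run_pipeline(cfg, d2, write_images = FALSE)
  for (f in list.files(d1, pattern = "\\.csv$")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
  # a different seed changes the noisy results
  d3 <- withr::local_tempdir()
  cfg2 <- cfg
  cfg2$seed <- 4L
  r3 <- run_pipeline(cfg2, d3, write_images = FALSE)
  expect_false(identical(r1$kinetics$estimate, r3$kinetics$estimate))
  # outputs exist and estimates are sane
  expect_true(all(c("iq_metrics.csv", "kinetics.csv",
                    "comparison_regions.csv") %in% list.files(d1)))
  logan <- r1$kinetics[r1$kinetics$method == "logan_bp_nd", ]
  expect_true(all(abs(logan$estimate / logan$truth - 1) < 0.25))
})

test_that("pipeline config without a seed is rejected up front", {
  cfg <- demo_config(1)
  cfg$seed <- NULL
  expect_error(run_pipeline(cfg, tempfile()), "seed")
})

test_that("round-trip IO preserves images and TACs", {
  ph <- single_sphere_phantom()
  g <- small_grid(c(32L, 32L, 24L), 2)
  img <- apply_psf(rasterize_phantom(ph, g, subsample = 2), 4)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_image_nifti(img, path)
  back <- read_image_nifti(path)
  expect_equal(back$grid$voxel_size, g$voxel_size, tolerance = 1e-6)
  expect_equal(back$values, img$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(file.exists(paste0(path, ".json")))

  sch <- brain_pet_schedule("16-frame")
  ref <- simulate_reference_tac(sch)
  tgt <- simulate_srtm_tac(ref, 1, 0.1, 2, region = "striatum")
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_tacs(list(ref, tgt), tpath)
  back_tacs <- read_tacs(tpath)
  expect_equal(back_tacs$striatum$values, tgt$values)
  expect_equal(back_tacs$reference$schedule$duration, sch$duration)
})
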