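#' Add proportional frame noise to a TAC
#'
#' Adds independent zero-mean Gaussian noise with standard deviation
#' `cv * |value|` to every frame. Used to emulate regional TAC noise when
#' validating the Logan estimator.
#'
#' @param tc A [tac()].
#' @param cv Proportional noise level (e.g. 0.05 for 5%).
#' @param seed Integer seed (required; determinism contract).
#' @return A noisy [tac()].
#' @export
add_tac_noise <- function(tc, cv, seed) {
  stopifnot(inherits(tc, "tac"), is.finite(cv), cv >= 0)
  if (missing(seed) || !is.finite(seed)) stop("explicit 'seed' required")
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  out <- tac(tc$schedule,
             tc$values + stats::rnorm(length(tc$values)) * cv * abs(tc$values),
             region = tc$region)
  attr(out, "ref_params") <- attr(tc, "ref_params")
  out
}

#' Default demonstration configuration
#'
#' A self-contained configuration for [run_pipeline()]: the six-sphere
#' contrast phantom at 3.88:1 contrast on a 128 x 128 x 89 grid (35.6 cm
#' in-plane FOV, 2.78 mm slices), two emulated scanners differing in PSF
#' width and noise level, high- (135 million prompts, one realization) and
#' low-count (12 million prompts, five replicates) noise conditions, and a
#' 16-frame 60-min kinetic protocol with three target regions of known
#' binding potential.
#'
#' @param seed Integer seed driving all randomness in the pipeline run.
#' @return A nested list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed) {
  if (missing(seed)) stop("config requires an explicit seed")
  list(
    seed = as.integer(seed),
    phantom = list(
      background_concentration = 4.8, contrast = 3.88, ring_radius = 35,
      cylinder_radius = 108, cylinder_height = 186,
      matrix = c(128L, 128L, 89L), in_plane_fov = 356,
      slice_thickness = 2.78, subsample = 2L,
      layout_radius = 85, margin = 15,
      high_count_prompts = 135e6, low_count_prompts = 12e6,
      low_count_replicates = 5L
    ),
    scanners = list(
      list(label = "hrrt_like", psf_fwhm = 3.0, tac_noise_cv = 0.05),
      list(label = "petmr_like", psf_fwhm = 4.5, tac_noise_cv = 0.03)
    ),
    kinetics = list(
      schedule = "16-frame", t_star = 20,
      reference = list(amplitude = 20, alpha = 2, beta = 1.2),
      regions = list(
        list(name = "caudate", r1 = 1.0, k2 = 0.1, bp_nd = 2.5),
        list(name = "putamen", r1 = 1.05, k2 = 0.1, bp_nd = 3.0),
        list(name = "cortex", r1 = 0.9, k2 = 0.1, bp_nd = 0.4)
      ),
      # FDG-like branch: accumulating tracer, ratio to reference over the
      # last 30 min of a 17-frame protocol.
      fdg = list(
        ratio_window_minutes = 30,
        reference = list(amplitude = 20, alpha = 0.6, beta = 80),
        regions = list(
          list(name = "putamen", uptake_ratio = 1.7),
          list(name = "caudate", uptake_ratio = 1.6),
          list(name = "medial_front_gyrus", uptake_ratio = 1.3)
        )
      )
    )
  )
}

config_error <- function(path, msg) {
  stop(sprintf("config schema violation at %s: %s", path, msg), call. = FALSE)
}

check_num <- function(x, path, min = -Inf) {
  if (is.null(x) || !is.numeric(x) || !all(is.finite(x)))
    config_error(path, "must be a finite number")
  if (any(x < min)) config_error(path, sprintf("must be >= %g", min))
  x
}

#' Validate a pipeline configuration
#'
#' Checks the schema of a [run_pipeline()] configuration; violations are
#' reported with the offending field path. A seed is mandatory (no silent
#' default).
#'
#' @param config Nested configuration list (see [demo_config()]).
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) config_error("config", "must be a list")
  if (is.null(config$seed))
    config_error("config$seed", "missing; an explicit seed is required")
  check_num(config$seed, "config$seed")
  ph <- config$phantom
  if (!is.list(ph)) config_error("config$phantom", "must be a list")
  check_num(ph$background_concentration,
            "config$phantom$background_concentration", min = 1e-12)
  check_num(ph$contrast, "config$phantom$contrast", min = 1e-12)
  check_num(ph$matrix, "config$phantom$matrix", min = 1)
  check_num(ph$in_plane_fov, "config$phantom$in_plane_fov", min = 1e-12)
  check_num(ph$slice_thickness, "config$phantom$slice_thickness", min = 1e-12)
  check_num(ph$subsample, "config$phantom$subsample", min = 1)
  check_num(ph$high_count_prompts, "config$phantom$high_count_prompts",
            min = 1)
  check_num(ph$low_count_prompts, "config$phantom$low_count_prompts", min = 1)
  check_num(ph$low_count_replicates, "config$phantom$low_count_replicates",
            min = 1)
  if (!is.list(config$scanners) || !length(config$scanners))
    config_error("config$scanners", "must be a non-empty list")
  for (i in seq_along(config$scanners)) {
    sc <- config$scanners[[i]]
    p <- sprintf("config$scanners[[%d]]", i)
    if (is.null(sc$label) || !nzchar(sc$label))
      config_error(paste0(p, "$label"), "missing")
    check_num(sc$psf_fwhm, paste0(p, "$psf_fwhm"), min = 0)
    check_num(sc$tac_noise_cv, paste0(p, "$tac_noise_cv"), min = 0)
  }
  kin <- config$kinetics
  if (!is.list(kin)) config_error("config$kinetics", "must be a list")
  if (!kin$schedule %in% c("16-frame", "17-frame"))
    config_error("config$kinetics$schedule",
                 "must be '16-frame' or '17-frame'")
  check_num(kin$t_star, "config$kinetics$t_star", min = 0)
  for (i in seq_along(kin$regions)) {
    rg <- kin$regions[[i]]
    p <- sprintf("config$kinetics$regions[[%d]]", i)
    if (is.null(rg$name)) config_error(paste0(p, "$name"), "missing")
    check_num(rg$r1, paste0(p, "$r1"), min = 1e-12)
    check_num(rg$k2, paste0(p, "$k2"), min = 1e-12)
    check_num(rg$bp_nd, paste0(p, "$bp_nd"), min = 0)
  }
  if (!is.null(kin$fdg)) {
    check_num(kin$fdg$ratio_window_minutes,
              "config$kinetics$fdg$ratio_window_minutes", min = 1e-12)
    for (i in seq_along(kin$fdg$regions)) {
      rg <- kin$fdg$regions[[i]]
      p <- sprintf("config$kinetics$fdg$regions[[%d]]", i)
      if (is.null(rg$name)) config_error(paste0(p, "$name"), "missing")
      check_num(rg$uptake_ratio, paste0(p, "$uptake_ratio"), min = 1e-12)
    }
  }
  invisible(config)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = FALSE)
  }
  validate_config(config)
  config
}

phantom_from_config <- function(ph) {
  contrast_phantom(background_concentration = ph$background_concentration,
                   contrast = ph$contrast,
                   ring_radius = ph$ring_radius %||% 35,
                   cylinder_radius = ph$cylinder_radius %||% 108,
                   cylinder_height = ph$cylinder_height %||% 186)
}

#' Run the full simulation and comparison pipeline
#'
#' Executes the end-to-end workflow for a pair (or more) of emulated
#' scanners: rasterize the digital contrast phantom, blur with each
#' scanner's PSF, add high- and low-count noise, compute the image-quality
#' metrics; simulate reference and target TACs, add scanner-specific frame
#' noise, fit the reference-region Logan model and late-window ratios; and
#' compare the first two scanners region by region. All randomness derives
#' from `config$seed`; a fixed seed gives byte-identical CSV outputs.
#'
#' Outputs written to `output_dir`: `iq_metrics.csv`, `tacs_<scanner>.csv`,
#' `kinetics.csv`, `comparison_regions.csv`, `comparison_means.csv`,
#' `phantom_<scanner>.nii.gz` (+ JSON sidecars), `roi_set.json`,
#' `provenance.json`.
#'
#' @param config Configuration list (see [demo_config()]) or path to a JSON
#'   file with the same structure.
#' @param output_dir Output directory (created if needed).
#' @param write_images If `FALSE`, skips the NIfTI phantom images.
#' @return Invisibly, a list with the in-memory results (`iq_metrics`,
#'   `kinetics`, `comparison`, `files`).
#' @export
run_pipeline <- function(config, output_dir, write_images = TRUE) {
  config <- read_config(config)
  if (missing(output_dir) || is.null(output_dir))
    stop("output_dir is required")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  ph_cfg <- config$phantom
  phantom <- phantom_from_config(ph_cfg)
  grid <- build_grid(ph_cfg$matrix, ph_cfg$in_plane_fov,
                     ph_cfg$slice_thickness)
  truth_img <- rasterize_phantom(phantom, grid,
                                 subsample = ph_cfg$subsample)
  files <- character()

  iq_rows <- list()
  for (si in seq_along(config$scanners)) {
    sc <- config$scanners[[si]]
    blurred <- apply_psf(truth_img, sc$psf_fwhm)
    rois <- build_roi_set(blurred, phantom,
                          layout_radius = ph_cfg$layout_radius %||% 85,
                          margin = ph_cfg$margin %||% 15)
    if (si == 1L) {
      roi_path <- file.path(output_dir, "roi_set.json")
      write_roi_set(rois, roi_path)
      files <- c(files, roi_path)
    }
    if (write_images) {
      img_path <- file.path(output_dir,
                            sprintf("phantom_%s.nii.gz", sc$label))
      write_image_nifti(blurred, img_path)
      files <- c(files, img_path)
    }
    conditions <- list(
      list(condition = "noiseless", prompts = NA_real_, replicate = NA_integer_,
           img = blurred))
    high <- add_noise(blurred, noise_model(ph_cfg$high_count_prompts,
                                           seed = seed + 1000L * si))
    conditions[[2L]] <- list(condition = "high_count",
                             prompts = ph_cfg$high_count_prompts,
                             replicate = 1L, img = high)
    for (r in seq_len(ph_cfg$low_count_replicates)) {
      low <- add_noise(blurred, noise_model(ph_cfg$low_count_prompts,
                                            seed = seed + 1000L * si + r))
      conditions[[length(conditions) + 1L]] <-
        list(condition = "low_count", prompts = ph_cfg$low_count_prompts,
             replicate = r, img = low)
    }
    for (cond in conditions) {
      res <- analyze_phantom(cond$img, rois)
      iq_rows[[length(iq_rows) + 1L]] <- cbind(
        scanner = sc$label, condition = cond$condition,
        target_prompts = cond$prompts, replicate = cond$replicate, res)
    }
  }
  iq_metrics <- do.call(rbind, iq_rows)
  iq_path <- file.path(output_dir, "iq_metrics.csv")
  utils::write.csv(iq_metrics, iq_path, row.names = FALSE)
  files <- c(files, iq_path)

  kin <- config$kinetics
  schedule <- brain_pet_schedule(kin$schedule)
  ref_par <- kin$reference
  ref <- simulate_reference_tac(schedule, amplitude = ref_par$amplitude,
                                alpha = ref_par$alpha, beta = ref_par$beta)
  kin_rows <- list()
  records <- list()
  for (si in seq_along(config$scanners)) {
    sc <- config$scanners[[si]]
    ref_noisy <- add_tac_noise(ref, sc$tac_noise_cv,
                               seed = seed + 100000L + 1000L * si)
    scanner_tacs <- list(ref_noisy)
    reg_names <- character(); reg_values <- numeric()
    for (ri in seq_along(kin$regions)) {
      rg <- kin$regions[[ri]]
      target <- simulate_srtm_tac(ref, rg$r1, rg$k2, rg$bp_nd,
                                  region = rg$name)
      target <- add_tac_noise(target, sc$tac_noise_cv,
                              seed = seed + 100000L + 1000L * si + ri)
      scanner_tacs[[length(scanner_tacs) + 1L]] <- target
      fit <- logan_bpnd(target, ref_noisy, t_star = kin$t_star)
      kin_rows[[length(kin_rows) + 1L]] <- data.frame(
        scanner = sc$label, method = "logan_bp_nd", region = rg$name,
        truth = rg$bp_nd, estimate = fit$bp_nd, t_star = fit$t_star,
        r_squared = fit$r_squared)
      reg_names <- c(reg_names, rg$name)
      reg_values <- c(reg_values, fit$bp_nd)
    }
    if (!is.null(kin$fdg)) {
      fdg_sch <- brain_pet_schedule("17-frame")
      fp <- kin$fdg$reference
      fdg_ref <- simulate_reference_tac(fdg_sch, amplitude = fp$amplitude,
                                        alpha = fp$alpha, beta = fp$beta,
                                        region = "fdg_reference")
      fdg_ref_noisy <- add_tac_noise(fdg_ref, sc$tac_noise_cv,
                                     seed = seed + 200000L + 1000L * si)
      scanner_tacs[[length(scanner_tacs) + 1L]] <- fdg_ref_noisy
      for (ri in seq_along(kin$fdg$regions)) {
        rg <- kin$fdg$regions[[ri]]
        target <- tac(fdg_sch, rg$uptake_ratio * fdg_ref$values,
                      region = paste0("fdg_", rg$name))
        target <- add_tac_noise(target, sc$tac_noise_cv,
                                seed = seed + 200000L + 1000L * si + ri)
        scanner_tacs[[length(scanner_tacs) + 1L]] <- target
        rat <- ratio_last_window(target, fdg_ref_noisy,
                                 window_minutes = kin$fdg$ratio_window_minutes)
        kin_rows[[length(kin_rows) + 1L]] <- data.frame(
          scanner = sc$label, method = "late_window_ratio",
          region = rg$name, truth = rg$uptake_ratio, estimate = rat$ratio,
          t_star = NA_real_, r_squared = NA_real_)
      }
    }
    tac_path <- file.path(output_dir, sprintf("tacs_%s.csv", sc$label))
    write_tacs(scanner_tacs, tac_path)
    files <- c(files, tac_path)
    records[[sc$label]] <- scanner_record(sc$label, reg_names, reg_values,
                                          subject = "sim1",
                                          tracer = "sim_tracer")
  }
  kinetics <- do.call(rbind, kin_rows)
  kin_path <- file.path(output_dir, "kinetics.csv")
  utils::write.csv(kinetics, kin_path, row.names = FALSE)
  files <- c(files, kin_path)

  comparison <- NULL
  if (length(records) >= 2L) {
    comparison <- scanner_ratio(records[[1L]], records[[2L]])
    cmp_path <- file.path(output_dir, "comparison_regions.csv")
    utils::write.csv(comparison$regions, cmp_path, row.names = FALSE)
    means_path <- file.path(output_dir, "comparison_means.csv")
    utils::write.csv(comparison$tracer_means, means_path, row.names = FALSE)
    files <- c(files, cmp_path, means_path)
  }

  prov <- list(package = "petiq",
               version = as.character(utils::packageVersion("petiq")),
               seed = seed, config = config,
               deviation_definition = "|ratio - 1| x 100")
  prov_path <- file.path(output_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, prov_path)

  invisible(list(iq_metrics = iq_metrics, kinetics = kinetics,
                 comparison = comparison, files = files))
}
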