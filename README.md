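# petiq

Image-quality metrics and reference-region kinetics for cross-validating
PET scanners, with a focus on brain imaging.

When a site replaces a dedicated brain PET scanner with a newer system, the
two must be compared quantitatively before longitudinal studies can span
them. The standard toolkit for that comparison is (a) a contrast phantom —
a warm cylinder with hot and cold spheres — analysed NEMA-style, and (b)
dynamic human-style scans quantified with reference-region kinetic models.
`petiq` implements both analyses end to end, together with a digital
phantom and TAC simulator carrying exact ground truth, so the whole
pipeline is testable without any scanner data.

## What it computes

For a sphere of measured mean concentration $C_\text{sphere}$, measured
background $C_\text{bg}$ (mean of 60 background-ROI means per sphere size)
and true concentrations $A_\text{hot}$, $A_\text{bg}$:

- **Hot recovery coefficient**
  $\mathrm{RC_{hot}} = \dfrac{C_\text{sphere}/C_\text{bg} - 1}{A_\text{hot}/A_\text{bg} - 1} \times 100\%$
- **Cold recovery coefficient**
  $\mathrm{RC_{cold}} = \left(1 - C_\text{sphere}/C_\text{bg}\right) \times 100\%$
- **% background variability** — sample CoV of the 60 background-ROI means
- **Voxel noise (%)** — CoV of individual voxel values pooled over the
  background ROIs, per replicate
- **RC-versus-noise trajectories** over iteration-indexed image series,
  and **line profiles** normalized to injected activity
- **Logan graphical analysis** with a reference region: the late-time
  slope of $\int_0^t C_T/C_T$ vs $\int_0^t C_R/C_T$ is the distribution
  volume ratio (DVR), and $\mathrm{BP_{ND}} = \mathrm{DVR} - 1$
- **Late-window activity ratios** (e.g. last 30 min, FDG-style) and
  **cross-scanner comparison reports** (per-region ratios,
  $|\mathrm{ratio}-1|\times100$ deviations, per-tracer subject means)

The simulator provides the six-sphere contrast phantom (inner diameters
9.9–31.3 mm, 3.88:1 hot contrast), Gaussian PSF blurring with an analytic
blurred-sphere oracle, count-dependent Gaussian noise (bit-reproducible
under a seed), and SRTM forward simulation of target TACs with known
BP_ND on the standard 16- and 17-frame 60-min schedules.

## Worked example

```r
library(petiq)

phantom <- contrast_phantom()                    # six spheres, 3.88:1
grid    <- build_grid(c(128, 128, 89), in_plane_fov = 356,
                      slice_thickness = 2.78)    # 2.781 mm voxels
img     <- rasterize_phantom(phantom, grid, subsample = 4)
blurred <- apply_psf(img, fwhm = 4.5)            # scanner-like resolution
noisy   <- add_noise(blurred, noise_model(target_prompts = 135e6, seed = 1))

rois <- build_roi_set(blurred, phantom)          # NEMA-style ROI scheme
iq   <- analyze_phantom(noisy, rois)
subset(iq, mode == "single_slice",
       select = c(diameter_mm, polarity, rc_pct,
                  bg_variability_pct, voxel_noise_pct))
#>    diameter_mm polarity rc_pct bg_variability_pct voxel_noise_pct
#> 1          9.9      hot   59.1              1.582            5.21
#> 3         12.4      hot   73.1              1.071            5.04
#> 5         15.4      hot   73.5              1.082            5.05
#> 7         19.8      hot   82.2              0.785            5.09
#> 9         24.8     cold   86.3              0.657            5.12
#> 11        31.3     cold   88.7              0.529            5.12
```

Recovery falls with sphere size (partial volume), background variability is
1–2% and voxel noise ~5% at the high count level — the familiar pattern for
a high-count phantom frame. Kinetics:

```r
sch <- brain_pet_schedule("16-frame")            # 4x60, 3x120, 8x300, 1x600 s
ref <- simulate_reference_tac(sch)               # gamma-variate bolus
tgt <- simulate_srtm_tac(ref, r1 = 1, k2 = 0.1, bp_nd = 2.5,
                         region = "putamen")
logan_bpnd(add_tac_noise(tgt, 0.05, seed = 2),
           add_tac_noise(ref, 0.05, seed = 3), t_star = 20)
#> logan_fit: DVR = 3.459, BP_ND = 2.459 (t* = 20 min, 7 points, R2 = 0.99859)
```

The fit recovers the simulated BP_ND of 2.5 within ~2% under 5% frame
noise. `run_pipeline(demo_config(seed), out_dir)` chains everything —
phantom simulation, IQ metrics at high/low count levels, TAC simulation,
Logan and ratio quantification for two emulated scanners, and the
cross-scanner comparison — into tidy CSVs plus NIfTI images, all
reproducible from the single seed. A thin CLI with the same stages lives at
`inst/cli/petiq` (subcommands `simulate-phantom`, `analyze-phantom`,
`trajectory`, `simulate-tacs`, `fit-logan`, `ratios`, `profile`, `compare`,
`run-all`).

## Documentation

The methods vignette (`vignettes/petiq-methods.Rmd`) describes the models
and their assumptions, the ROI-placement and noise-model design decisions,
numerical choices and known limitations.
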