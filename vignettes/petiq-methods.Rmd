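---
title: "Methods: phantom image-quality metrics and reference-region kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom image-quality metrics and reference-region kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`petiq` implements the quantitative analyses used to cross-validate PET
scanners for brain imaging: contrast-phantom image-quality metrics
(hot/cold sphere recovery coefficients, percent background variability,
voxel-level noise, recovery-versus-noise iteration trajectories, line
profiles), reference-region kinetic quantification (Logan graphical
analysis for BP~ND~, late-window activity ratios), and cross-scanner
comparison reports. Because real scanner data cannot be bundled, the
package ships a digital stand-in: a voxelized contrast phantom with
analytic ground truth and a kinetic forward simulator with known binding
potentials. Everything downstream of reconstruction is in scope; tomographic
reconstruction itself (OSEM, TOF, attenuation, scatter) is not — iteration
series and count levels enter only as labelled inputs.

# The digital contrast phantom

The phantom is a warm cylinder (default interior radius 108 mm, height
186 mm, ~6.8 L) containing six spheres of inner diameters 9.9, 12.4, 15.4,
19.8, 24.8 and 31.3 mm centred on a 35 mm ring in the central transaxial
plane. The four smallest are hot at a 3.88:1 concentration ratio to the
background; the two largest are water-filled (cold). The default background
concentration of 4.8 kBq/ml puts ~29 MBq into the phantom. The sphere ring
radius and cylinder dimensions are nominal values for this phantom class;
only the sphere diameters, the contrast ratio and the background ROI count
matter to the metrics.

Rasterization (`rasterize_phantom()`) assigns each voxel the
volume-fraction-weighted mixture of the adjoining compartments. Interior
voxels are exact; voxels cut by a surface are subdivided into
`subsample^3` points (default 4, i.e. 64 points). Fractional coverage
converges as the subsampling grows; at the default the total rasterized
activity matches the closed-form cylinder/sphere volumes to well under
0.5%.

Scanner resolution is emulated by `apply_psf()`, an isotropic Gaussian
convolution in world units. Numerical choices: the convolution is
separable; the kernel is sampled at voxel centres, truncated at four
standard deviations and renormalized to unit sum (so activity of interior
objects is conserved to numerical precision); the boundary is zero-padded,
consistent with a phantom surrounded by air. One Gaussian FWHM stands in
for the combined effect of intrinsic resolution, reconstruction and
post-filtering — adequate for validating metric code, not a scanner model.

## The analytic oracle

A uniform sphere of radius $R$ convolved with an isotropic Gaussian of
width $\sigma$ has the closed-form radial profile

$$ f(r) = \tfrac{1}{2}\!\left[\operatorname{erf}\!\frac{R-r}{\sigma\sqrt2}
 + \operatorname{erf}\!\frac{R+r}{\sigma\sqrt2}\right]
 - \frac{\sigma}{r\sqrt{2\pi}}\!\left[e^{-(R-r)^2/2\sigma^2}
 - e^{-(R+r)^2/2\sigma^2}\right], $$

with the $r\to0$ limit
$\operatorname{erf}(R/\sigma\sqrt2)-\sqrt{2/\pi}\,(R/\sigma)\,
e^{-R^2/2\sigma^2}$. The test suite validates this form once against direct
numerical 3-D convolution, then uses it (plus an erf edge model for the
cylinder wall) as an independent prediction of every ROI mean on the
noiseless blurred phantom. Because the pipeline's voxels hold voxel
averages, the oracle (`analytic_roi_mean()`) averages the closed form over
each ROI voxel rather than sampling it at voxel centres; point sampling
alone leaves a systematic half-percent-scale gap for the smallest sphere
that is a property of grid sampling, not of either implementation.

## Noise model

Reconstructed-image noise is emulated, not derived: additive zero-mean
Gaussian with voxel standard deviation

$$ \mathrm{sd}(v) = s\,\sqrt{\max(v,0)}\,/\sqrt{N_\text{prompts}}, $$

proportional to the square root of the local mean and inversely
proportional to the square root of the frame's prompt count. The scale
$s = 1300$ (default) was chosen once so that a 4.8 kBq/ml background shows
roughly 5% voxel noise at 135 million prompts and ~17% at 12 million — the
two count levels used for high/low-count characterization (one realization
high, five replicates low). The true noise distribution of any particular
reconstruction is neither known nor modelled; what the simulator guarantees
is the first two moments, the $1/\sqrt{N}$ count scaling, and bit-exact
reproducibility under a fixed seed. Noisy images may contain small negative
values: non-negativity is a property of particular reconstruction
algorithms, and the metrics must tolerate negatives.

Consequently, passing tests demonstrate correctness of the measurement
code under controlled conditions — they do not certify behaviour on real
reconstructions with correlated noise textures, Gibbs overshoot from PSF
modelling, or attenuation/scatter residuals (the recovery-coefficient code
deliberately does not clamp values above 100% for exactly the Gibbs case).

# ROI geometry

Following the standard protocol, each sphere is measured two ways: a
single-slice circular ROI with diameter equal to the physical inner
diameter, placed on the transaxial plane in which the sphere is most
visible, and a spherical VOI of the same diameter. "Most visible" is
operationalized as the extremal in-ROI mean (maximal for hot, minimal for
cold spheres) among slices within one sphere radius of the geometric
centre slice, with ties resolved toward the geometric centre and then the
lower index. Voxel membership is binary centre-inclusion — matching common
ROI-tool behaviour and keeping the metric inputs unambiguous; fractional
weighting is deliberately not used.

The protocol prescribes 12 background ROIs per sphere size on the central
plane plus replicas at ±1 cm and ±2 cm axial offsets — 60 per sphere size —
but no coordinates. The package places the 12 centres uniformly on a
configurable circle (default radius 85 mm, start angle 15° so the centres
interleave the 60°-spaced spheres), concentric across sphere sizes, and
verifies declaratively that every ROI lies inside the cylinder and keeps a
configurable margin (default 15 mm) from every sphere surface; an
infeasible layout is a hard geometry error that lists the violating ROIs.
Axial offsets are converted to the nearest slice (slice thickness differs
between reconstructions); the indices actually used are recorded in the
output metadata.

# Image-quality metrics

With $C$ measured and $A$ true concentrations,

$$ \mathrm{RC_{hot}} = \frac{C_\text{sphere}/C_\text{bg} - 1}
   {A_\text{hot}/A_\text{bg} - 1}\times100\%,\qquad
   \mathrm{RC_{cold}} = \left(1 - \frac{C_\text{sphere}}{C_\text{bg}}\right)
   \times100\%. $$

$C_\text{bg}$ is the mean of the $K=60$ background-ROI means for that
sphere size; percent background variability is their sample coefficient of
variation ($K-1$ denominator). Voxel noise is the coefficient of variation
of individual voxel values pooled across the same 60 background ROIs, with
the mean over those same voxels in the denominator (the protocol reuses the
background symbol; both numbers are reported). For replicate sets, noise
metrics are computed per replicate and then averaged — voxels are never
pooled across realizations. Iteration trajectories simply apply the full
analysis to an ordered image series with no cross-iteration smoothing.

Line profiles are sampled nearest-voxel ("single voxel width", no
interpolation) at a spacing equal to the smallest in-plane voxel size and
normalized by the injected activity. `sensitivity_percent()` is a pure
unit-conversion utility between the cps/kBq and percent reporting
conventions, including renormalization from the full 70 cm line source to
an in-FOV length.

# Kinetics

The forward simulator produces a reference-region curve as a gamma variate
$C_R(t)=A\,t^\alpha e^{-t/\beta}$ (defaults $A=20$ kBq/ml/min^α^,
$\alpha=2$, $\beta=1.2$ min: a bolus peaking at 2.4 min with fast washout,
typical of a reversible ^11^C tracer in a reference region) and target
curves through the simplified reference tissue model

$$ C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_{2a})
   \left[C_R \otimes e^{-k_{2a} t}\right](t),\qquad
   k_{2a} = \frac{k_2}{1 + \mathrm{BP_{ND}}}. $$

All forward models are evaluated on a 1 s grid (frame-average error well
below 0.5% for the shortest 60 s frames) and then averaged over the frame
schedule; two standard 60-min schedules are built in (16-frame for
reversible ^11^C tracers, 17-frame for FDG). SRTM is the *simulator only*;
the package never fits it.

Quantification uses the reference-region Logan plot: ordinary least
squares of $\int_0^{t}C_T/C_T$ against $\int_0^{t}C_R/C_T$ over frames with
mid-times $\ge t^\*$; the slope is the distribution volume ratio and
$\mathrm{BP_{ND}} = \mathrm{DVR}-1$. Design choices, each exposed and
reported in the fit object rather than silently assumed:

* the reference-efflux term $C_R/(k_2'\,C_T)$ is omitted by default and
  included when `k2_ref` is supplied — at late $t^\*$ its influence is
  small, and a default had to be declared;
* $t^\* = 20$ min by default, configurable; the fit reports the maximum
  relative residual of the line as a linearity diagnostic for choosing
  $t^\*$;
* integrals are frame-duration-weighted piecewise-constant sums — exact for
  frame-average data, which is what TACs are;
* plain OLS, no errors-in-variables correction: the well-known
  noise-induced underestimation of DVR at low signal-to-noise is
  documented, not corrected;
* all inputs are assumed decay-corrected to a common origin; the toolkit
  performs no decay correction.

With the fast default reference kinetics the plot is effectively linear by
20 min and noiseless simulations over BP~ND~ ∈ {0.5, 2, 4}, $R_1$ ∈
{0.8, 1.2}, $k_2$ ∈ {0.05, 0.15}/min recover BP~ND~ with sub-percent bias;
a slowly equilibrating configuration (used in the tests) shows the expected
monotone transient bias in $t^\*$. Late-window ratios are duration-weighted
means over the frames whose mid-times fall in the final window (default
30 min; for the 17-frame schedule this is exactly the last six 300 s
frames) — meaningful for an accumulating FDG-like tracer, which the demo
pipeline simulates as a slow gamma variate scaled by region-specific uptake
ratios, not for a fast-washout bolus.

# Cross-scanner comparison and the pipeline

`scanner_ratio()` matches regional values (BP~ND~ or ratios) between two
scanners on subject, tracer and region; missing regions are an error naming
the region. Deviation is defined as $|\mathrm{ratio}-1|\times100$ (the
convention is stated in the report header since prose like "deviations
below 10%" does not pin down a formula), and per-tracer means across
subjects are means of per-subject ratios, not ratios of means.

`run_pipeline()` ties the stages together from a single validated
configuration (JSON or list; schema violations are reported with field
paths; a seed is mandatory with no silent default). Every random draw
derives from that seed, so a fixed configuration yields byte-identical CSV
outputs. The bundled `demo_config()` emulates two scanners differing in
PSF width (3.0 vs 4.5 mm) and TAC noise (5% vs 3%) on the 128×128×89
phantom-reconstruction grid, with one high-count realization and five
low-count replicates. A thin command-line wrapper (`inst/cli/petiq`)
exposes the stages as subcommands.

# Problem sizes and conventions

Default problem sizes were chosen so the whole validation suite runs
comfortably on a single CPU: phantom analyses on the 128×128×89
(2.781 mm) grid, oracle-equivalence checks on a 200×200×160 (1.22 mm)
grid with rasterization subsample 4, Logan validation with 100 noisy
replicates at 5% frame noise. Coordinates are world millimetres with a
voxel-centre convention and 1-based voxel indices (R convention); the
axial direction is z; the grid is centred on the origin unless an origin
is given. Images are written as NIfTI-1 with correct `pixdim` and a JSON
provenance sidecar; tables as tidy CSV keyed by scanner, condition,
replicate, sphere diameter, mode and region.

# Known limitations

* The Gaussian PSF and proportional-Gaussian noise are stand-ins: no
  spatially varying resolution, no correlated noise, no Gibbs ringing, no
  reconstruction non-negativity.
* Single-slice ROI placement is sensitive to where sphere centres fall
  relative to slice boundaries (the motivation for also providing the
  spherical-VOI mode, which yields systematically lower hot-sphere RCs on
  blurred images).
* Logan BP~ND~ from noisy data is biased low by construction (OLS on
  noisy ordinates); the package reports, and the vignette states, rather
  than corrects this.
* Human-style analyses accept user-supplied label maps; no template
  registration or motion correction is provided.
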