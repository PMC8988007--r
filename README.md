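# telodrop

Quantitative image analysis of telomeric shelterin–DNA condensates, for
researchers studying liquid–liquid phase separation (LLPS) of telomere-binding
proteins (TRF1, TRF2, and assembled shelterin complexes) in vitro and in
living cells. The package reimplements, as tested and reusable R functions,
the complete quantitative layer of such a study: droplet segmentation and
settled-volume quantification, saturation-concentration estimation, fusion
kinetics, anomalous-diffusion and first-passage analysis of telomere motion,
FRAP normalization, coalescence intensity conservation, dilute-phase scaling
model comparison, and 3D DNA-damage foci counting. Because raw microscopy
data for such experiments are rarely deposited, a seeded synthetic-data
module generates every input the pipeline consumes — with ground-truth tables
— so every estimator is testable end to end without any download.

## The models at the core

**Saturation concentration.** Settled condensate volume per coverslip area
grows linearly with protein concentration above the phase boundary. Fitting
V(c) = s·(c − c_sat) by ordinary least squares over conditions with
measurable volume, the x-intercept −b₀/b₁ estimates c_sat, with its standard
error from the coefficient covariance by the delta method.

**Anomalous diffusion.** Telomere trajectories follow
MSD(τ) = D·τ^α (2D, x and y summed) with α < 1 (subdiffusion). The fit is
OLS of log MSD on log τ; a known localization error σ_loc adds a constant
floor 2σ_loc² to the time-averaged MSD, which `fit_msd_powerlaw()` can
subtract before fitting (the standard static-error correction). First-passage
encounter times between two loci extrapolate the fitted law via
2·D·t^α = d².

**Droplet segmentation.** Phansalkar local adaptive thresholding,
T = μ·(1 + p·e^(−qμ) + k·(σ/r − 1)) over a circular window (defaults k = 0.25,
r = 0.5, p = 2, q = 10, radius 30 px), 8-connected labeling with a 10 px
minimum size, equivalent-ellipse semi-axes (a, b) from intensity-weighted
second moments, and volume V = (4/3)π·a·b·√(ab) with the axial semi-axis
taken as the geometric mean of the in-plane ones.

**Fusion kinetics.** A fusion event runs from the last frame with two
separate droplets to the first frame where the merged object appears
spherical (aspect ratio ≤ 1.1, sustained two frames); gel-like pairs that
never round up are reported censored, and `fusion_cdf()` builds the
empirical cumulative fusion probability with censoring.

**Dilute-phase scaling.** In a single-component (homotypic) system the
nucleoplasmic concentration c_dil saturates at c_sat as total concentration
rises; in a multicomponent (heterotypic) system it keeps rising sublinearly.
`fit_dilute_models()` fits both registered forms by nonlinear least squares
and selects by small-sample-corrected AIC (|ΔAICc| < 2 → indeterminate).

## Worked example

Generate subdiffusive telomere trajectories at the fitted law
(α = 0.54, D = 2.8×10⁻³ μm² s⁻ᵅ, 20 nm localization error), recover the
parameters, and extrapolate encounter times:

```r
library(telodrop)

sim <- sim_fbm_trajectories(alpha = 0.54, D_gen = 2.8e-3, n_traj = 200,
                            n_frames = 300, dt = 1, loc_noise = 0.02, seed = 1)
msd <- compute_msd(sim$trajectories)
fit <- fit_msd_powerlaw(msd, fit_range = c(2, 30), static_error = 0.02)
fit
#> MSD(tau) = D tau^alpha: alpha = 0.544 +/- 0.00038, D = 0.0028 +/- 2.9e-06
#> um^2 s^-alpha (29 lags, 2-30 s)

encounter_time(fit, c(2.4, 6.8))
#> # A tibble: 2 x 5
#>   separation_um mode             time_s time_days extrapolated
#>           <dbl> <chr>             <dbl>     <dbl> <lgl>
#> 1           2.4 relative_pair   347459.      4.02 TRUE
#> 2           6.8 relative_pair 16018486.    185.   TRUE
```

The recovered exponent matches the generative 0.54, and the extrapolation
says a telomere needs ~4 days to cover its typical nearest-neighbor distance
(2.4 μm) and ~200 days for the mean pairwise distance (6.8 μm) — telomeres
essentially never meet by diffusion alone.

Segment a synthetic droplet field and summarize settled volume per area (the
input to the c_sat fit):

```r
field <- sim_droplet_field(n_droplets = 12, snr = 10, seed = 1)
seg   <- segment_droplets(field$image)
summarize_field(seg$records, field_area_um2 = (256 * 0.106)^2,
                protein_conc_um = 8)
#> # A tibble: 1 x 7
#>   n_droplets total_volume_um3 total_volume_per_area field_area_um2 ...
#> 1         12             105.                 0.143           736.
```

All 12 rendered droplets are found; `fit_csat()` consumes a table of such
summaries across concentrations, and `autoplot()`/`plot_*()` functions
display MSD curves, FRAP recoveries, fusion CDFs, titrations and
dilute-phase fits.

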