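---
title: "Methods: quantifying telomeric condensates with telodrop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying telomeric condensates with telodrop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telodrop)
```

telodrop implements the quantitative layer of a telomere phase-separation
study: everything between raw fluorescence images (or particle tables) and
the numbers a paper reports. This vignette explains each model, the
parameters that matter, the synthetic-data generators the tests rest on, and
the numerical choices made where the methods literature leaves room.

## In vitro droplet quantification

Settled condensates are segmented with the Phansalkar local adaptive
threshold: a pixel is foreground when its value exceeds

$$T = \mu\,\bigl(1 + p\,e^{-q\mu} + k(\sigma/r - 1)\bigr),$$

with $\mu,\sigma$ the mean and SD over a circular window (radius 30 px by
default) and the published low-contrast constants $k=0.25$, $r=0.5$, $p=2$,
$q=10$. The formula presumes intensities normalized to $[0,1]$, so each
field is min–max normalized first. Windows are clipped at the image border
(normalized convolution with zero padding), computed by FFT; thresholds whose
magnitude falls below $10^{-9}$ are snapped to zero so that FFT round-off can
never out-compete an exactly constant background. Both circular and square
windows are implemented; circular is the default. Components are 8-connected
and those under 10 px are discarded. Droplets touching the field border are
retained — discarding them would bias settled volume per area low.

Per droplet, intensity-weighted second central moments give
equivalent-ellipse semi-axes $a \ge b$ (for a solid disc of radius $R$,
$a=b=R$; a $1/12$ px$^2$ term accounts for pixel extent). The settled droplet
is modeled as an ellipsoid whose axial semi-axis is the geometric mean of the
in-plane ones, $c=\sqrt{ab}$, so $V = \tfrac{4}{3}\pi a b \sqrt{ab}$. The
field summary $\sum V / \text{area}$ feeds the phase analysis.

Partition coefficients divide the background-subtracted mean intensity
inside a droplet mask by that of a background mask. The camera offset
defaults to 0; `"mode"` estimates it as the histogram mode of the background
region (the mode is read as the median of the modal bin, which is exact for
discrete backgrounds and unbiased for symmetric noise).

## Saturation concentration and phase behavior

Above the phase boundary, settled volume per area grows linearly with
protein concentration. `fit_csat()` fits OLS over conditions whose mean
volume exceeds `min_detectable` and reports the x-intercept
$\hat c_\mathrm{sat} = -b_0/b_1$ with a delta-method standard error. A
non-positive slope or fewer than three usable conditions are explicit
errors, not numbers. Volumes (not log volumes) are fit, matching the linear
model; the estimator is unbiased under multiplicative noise because the
noise enters with mean one (checked over 200 seeded series in the tests).

Reentrance along a DNA titration is classified from replicate means: an
interior maximum exceeding both endpoints by more than the pooled replicate
SD is `reentrant`; otherwise a Spearman rank correlation $|\rho|\ge 0.8$
labels a monotone trend, else `flat`. The rule is invariant to uniform
volume rescaling.

`local_concentration()` is pure unit arithmetic,
$c = n / (N_A \cdot \tfrac43\pi r^3)$ in micromolar, and is tested against an
independent mol/L conversion to 7 digits.

## Dilute-phase scaling: homotypic vs heterotypic

In a single-component system the dilute (nucleoplasmic) concentration
saturates at $c^\ast$ once condensates form; in a multicomponent system it
keeps rising sublinearly. The exact functional form of the heterotypic
stabilization curve is not uniquely fixed by the literature, so both models
live behind a registry (`register_dilute_model()`) and can be replaced
without touching the fitting code. The shipped forms are:

* homotypic: $c_\mathrm{dil} = \min(c_\mathrm{tot} + e,\; c^\ast)$, with an
  endogenous-protein offset $e \ge 0$ entering the total (this is why a
  homotypic curve measured over expressed protein need not be flat);
* heterotypic: $c_\mathrm{dil} = c_\mathrm{tot} - A\,c_\mathrm{tot}/(K + c_\mathrm{tot})$,
  strictly increasing and sublinear for $A \le K + c_\mathrm{tot}$.

Fitting uses Levenberg–Marquardt least squares with five jittered starts per
model; where the gradient is singular (a parameter without leverage, e.g.
$c^\ast$ above the sampled range) a bounded quasi-Newton minimization of the
RSS takes over. Model selection uses AICc with the standard evidence
threshold: $|\Delta \mathrm{AICc}| < 2$ is declared *indeterminate* rather
than a winner — which also covers the regime below the saturation point where
the two models coincide exactly. Selection accuracy is exercised in the tests
at 5% noise (at least 95 of 100 seeded series correct) and in the noiseless
limit (all correct).

## Fusion kinetics

A fusion event is scored from the per-frame aspect ratio of the largest
segmented object: contact is the last frame with two separate droplets, and
completion the first later frame whose aspect ratio is at or below
`ar_complete` sustained for `hold_frames` consecutive frames. The defaults
(1.1 and 2) operationalize "appears spherical": the tolerance is not a
published number, and a single-frame dip must not end an event under noise;
both are arguments. Events that never relax below the criterion (gel-like
multi-component droplets) return `completed = FALSE` and are censored by
`fusion_cdf()` — they stay in the denominator and never enter the numerator.

The fusion-movie generator renders two touching discs that merge into an
ellipse whose aspect ratio decays exponentially from 2, with the time
constant placed so the criterion is first met half a frame before the
nominal fusion time — the scored completion frame then falls on the intended
frame with maximal margin against rasterization error in the measured aspect
ratio. Recovery is within one frame interval across fusion times of 5–60 s
in the tests.

## Telomere motion

*Registration.* Whole-nucleus drift is removed by FFT cross-correlation
against the first frame with a quadratic subpixel peak fit (accurate to a
few hundredths of a pixel on rendered scenes) and bilinear resampling.
Plain cross-correlation is used rather than phase correlation: its smoother
peak makes the three-point parabola markedly more accurate on undersampled
fluorescence scenes. Featureless frames get zero shift and a flag.

*Detection.* Puncta are found with a scale-normalized Laplacian-of-Gaussian
filter at $\sigma = d/(2\sqrt2)/\text{pixel size}$ for an expected diameter
$d$ (0.5 μm default), thresholded at mean + 2 SD *of the filtered image*
(the filtered-image convention is the default; the raw-image alternative
would couple the threshold to background structure), with 3×3 quadratic
subpixel refinement.

*Linking.* Frame-to-frame assignment minimizes total squared displacement by
the Hungarian algorithm on the standard augmented cost matrix: links beyond
`max_link_um` (0.5 μm default) are forbidden and track birth/death costs
`max_link_um`². No gap closing — a missed detection terminates the track —
and tracks spanning less than half the movie are discarded. On frames of up
to six particles the assignment provably equals exhaustive-search matching
(tested).

*MSD and the power law.* The curve is the time-averaged squared displacement
per trajectory (x and y summed), ensemble-averaged with pair-count weights,
with lags capped at 25% of trajectory length. `fit_msd_powerlaw()` is OLS of
log MSD on log lag. Localization error of SD $\sigma_\mathrm{loc}$ (the 2D
error vector; a frozen trajectory reads $2\sigma_\mathrm{loc}^2$ at every
lag) adds a constant floor that biases the log–log slope of a subdiffusive
curve downward — with 20 nm error on a 2.8×10⁻³ μm² s⁻ᵅ, α = 0.54 law the
raw slope over 2–30 s lags drops by roughly 0.045 and the coefficient
inflates by about a fifth. The `static_error` argument subtracts the known
floor before fitting (the standard static-error correction); with it, both
parameters are recovered within their test tolerances (±0.03 on α, ±20% on
D across 20 seeded batches). The default is 0, i.e. the uncorrected fit.

*First passage.* `encounter_time()` inverts the fitted law. The default
`relative_pair` mode doubles the MSD (two independently subdiffusing loci),
solving $2Dt^\alpha = d^2$; `single_locus` is retained for sensitivity
analysis. These are order-of-magnitude extrapolations days beyond the
observed lags and carry an explicit `extrapolated` flag.

*FRAP.* Double normalization
$F_1 = (F/\langle F\rangle_\mathrm{pre})\,(\langle W\rangle_\mathrm{pre}/W)$
cancels acquisition photobleaching via the whole-cell reference $W$ exactly
(a constructed exponential reference decay changes nothing, per test), then a
full-scale rescale anchors the pre-bleach mean at 1 and the first post-bleach
point at exactly 0. A trace with no detectable bleach makes the rescale
degenerate; it is flagged and returned unrescaled rather than divided by
noise.

## Nuclear foci and intensity bookkeeping

Nuclei are segmented by Otsu's threshold (256-bin between-class variance,
equal to exhaustive search in tests), hole-filled, and size-filtered (20 μm²
in 2D, 50 μm³ in 3D). Labeling is 8-connected in 2D and 26-connected in 3D
throughout; the labeler is an iterative minimum-label propagation with
run-minimum sweeps along each axis, validated against flood fill.

Foci and telomeres are detected per z-slice with the same LoG filter,
thresholded on the 3D response, and 26-connect labeled; each object is
assigned to the nucleus containing its weighted centroid (objects outside
every nucleus are dropped — counting semantics are per nucleus).
Colocalization requires at least one shared voxel (`--coloc-min-voxels`
equivalent exposed as an argument) since the reference plugin's criterion is
not published. The damage classifier is the fraction of nuclei with strictly
more than 10 foci.

Coalescence bookkeeping predicts the post-merge integrated intensity as the
sum of the two pre-merge means (frames with two objects), with standard
errors of the means combined in quadrature. Integration uses a generous
circular aperture (4 detection σ) around each object centroid rather than
the raw threshold mask, since a truncated mask under-measures brighter
objects more and would fake non-conservation. The verdict tolerance is
2 × combined SE plus a 1% relative floor; the floor absorbs aperture
cross-talk and rendering residue in the noiseless limit, and is far below
any genuine violation the tests construct (≥ 33%).

The dilute-phase measurement masks detected telomeres (dilated 1 px) out of
the nucleoplasm before averaging; the image is blob-detected with the
outside of the nucleus filled at the nuclear mean so the nuclear rim cannot
fire the detector. A telomere mask covering more than half the nucleus
triggers a warning rather than silent nonsense.

## The synthetic-data module

Every generator takes an explicit integer seed and restores the global RNG
state; identical parameters and seed reproduce outputs bit-exactly. The
generators emulate:

* near-TIRF fields of settled droplets: blurred-edge discs (edge SD 1 px)
  on constant background with Poisson–Gaussian noise at a stated peak SNR
  (shot noise scaled so the peak-signal-to-shot-noise ratio equals `snr`,
  plus a read-noise floor of a quarter of that). Rendered profiles are
  truncated below 10⁻⁴ of peak — below any real camera's quantization — so a
  noiseless background is exactly constant;
* fusion movies (above), including permanently separated and gel-like pairs;
* fractional Brownian trajectories with exact fractional-Gaussian-noise
  increments by Davies–Harte circulant embedding (Cholesky fallback if the
  embedding fails), per-coordinate variance $D\,\tau^\alpha/2$, plus optional
  localization noise. Sample autocovariance matches the fGn formula within
  3–4 SE out to lag 10 at 10⁵ increments (tested);
* three-channel nuclear z-stacks (ellipsoid nuclei; telomere and damage-focus
  puncta as 3D Gaussians, with a chosen fraction of foci sharing voxels with
  telomeres) carrying per-nucleus truth counts;
* FRAP traces whose double-normalized form is exactly
  $m(1-e^{-t/\tau})$, with optional reference photobleaching and noise;
* dilute-phase series from the two registered generative models;
* coalescence movies with integrated intensities $I_1, I_2$ merging to
  $I_1+I_2$ (or a stated violating value, for negative controls);
* droplet-influx movies with a known partition-coefficient time constant.

What the generators do **not** emulate: optical point-spread anisotropy and
TIRF evanescent decay, camera-specific noise calibration, hydrodynamics of
fusion necks, chromatic aberration, or nuclear heterogeneity. Passing tests
therefore demonstrate estimator correctness on data obeying the stated
models, not robustness to every real-microscope artifact.

## Problem sizes and defaults

The test suite and the acceptance script run on deliberately modest sizes
chosen to exercise every code path at full statistical fidelity: 256 px
droplet fields, 200 trajectories × 300 frames (20 seeded batches for
parameter recovery), 50 seeded titrations per saturation-concentration
recovery, 10 fusion movies, 100 seeded series for model-selection accuracy,
and 2-nucleus z-stacks of 10 × 96 × 192 voxels (12 noiseless seeds plus
noisy ones). The effective pixel size defaults to 0.106 μm (EMCCD at 100×)
and appears, with a loud warning, whenever TIFF metadata is missing.

## Known limitations

* 2D segmentation only for in vitro droplets; volumes rest on the settled
  ellipsoid model, and the segmented mask includes the blurred rim, so
  per-droplet volumes run slightly above the hard-sphere truth on rendered
  fixtures (counts and trends are exact; the c_sat estimator consumes
  volumes linearly and is unaffected in expectation).
* The heterotypic dilute-phase form is a documented stand-in behind the
  registry, not a thermodynamic derivation.
* No gap closing in tracking; blinking objects fragment into tracks that the
  span filter may then discard.
* First-passage numbers are extrapolations by construction and should be
  read as orders of magnitude.
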