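---
title: "Methods: nanocage-based fluorescent-protein benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanocage-based fluorescent-protein benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and numerical
choices behind each analysis stage, the assumptions they rest on, and what
validation on synthetic data does and does not establish about real
microscopy data.

## The assay and its model

A 60-subunit dodecahedral protein nanocage tagged with one fluorescent
protein (FP) per subunit presents exactly 60 FP copies (120 with tandem
tags) in a ~26 nm particle — far below the diffraction limit, so a nanocage
images as a single point-spread-function (PSF)-shaped spot. Three
quantities are measured per FP, all on the same cells and imaging system:

1. **Brightness per molecule.** The background-corrected integrated
   intensity of a single nanocage spot, divided across FPs, is a
   molecule-by-molecule brightness comparison that is independent of
   expression level.
2. **Photostability.** The whole-cell fluorescence decay under continuous
   illumination, fitted by a single exponential; reported as the half-life
   `t½ = ln 2 / k`.
3. **Mobility.** Nanocages diffuse freely in cytoplasm; the diffusion
   coefficient from single-particle tracking (2D Brownian motion,
   `MSD = 4 D Δt`) checks that brightness differences are not aggregation
   artifacts, since `D` scales inversely with particle size at low Reynolds
   number.

The combined figure of merit is the **relative emission yield**: relative
brightness × photobleaching half-life at matched irradiance, proportional
to the photon budget an FP delivers before bleaching.

## The synthetic-data generator

No raw image data ships with this package; instead a forward model renders
ground-truth-annotated stacks, and every analysis stage is validated by
recovering known parameters.

**What it models.** Brownian trajectories with per-axis sub-step
displacements `N(0, 2 D Δt_sub)`; a Gaussian PSF integrated over each
camera pixel's area; motion blur by advancing each particle through
`n_blur_substeps` positions per exposure, each stamped with `1/n` of the
photon budget; continuous exponential bleaching of the expected photon
rate; Poisson shot noise on photons, then gain, additive Gaussian read
noise, constant offset, rounding and 16-bit saturation. Two optics presets
mirror the two acquisition regimes: spinning-disc confocal (27 nm pixels,
500 ms exposures, 200 nm FWHM PSF) for intensity/bleaching work and TIRF
(110 nm pixels, 85 frames per second) for tracking.

**Deliberate simplifications.** Bleaching acts on the ensemble expectation,
not on discrete FP on/off states — with 60 FPs per cage the ensemble mean
is what decay fits measure, and single-FP blinking is out of scope. There
is no evanescent-field depth (TIRF is treated as a thin 2D plane), no
super-resolution optics model, no FP maturation, no chromatic effects, no
cytoplasmic autofluorescence texture, and no cell-to-cell variability in
viscosity or expression. Consequently, synthetic recovery tests demonstrate
the *estimators* are unbiased and correctly implemented under the model's
assumptions; they cannot certify performance on real cells, where
background structure, focus drift and heterogeneity add error sources the
generator does not emulate. Real-data quantities reported in the field
(e.g. a cell-to-cell diffusion spread of ±0.2 µm² s⁻¹) are dominated by
biological variability that homogeneous simulations intentionally lack.

**Default camera** (all configurable): gain 1 count/photon, read noise 1.5
counts, offset 100 counts, 16-bit saturation — generic sCMOS-like values.

**Seeding.** One master seed; per-particle and per-stage sub-streams are
derived deterministically (`seed + 1000003·stream mod 2³¹−19`), so adding a
particle never perturbs existing trajectories, and a fixed seed re-renders
bit-identical stacks.

**Boundaries.** Reflecting by default (a confined cytoplasm region);
periodic offered for MSD studies free of edge effects. Both wrapped and
unwrapped (free-space) positions are kept: rendering uses wrapped
positions, displacement statistics use unwrapped ground truth.

## Spot quantification

**Model.** Elliptical (σx, σy, unrotated) 2D Gaussian plus constant offset,
five shape parameters plus amplitude. A single reported width is enough for
FWHM, but elliptical widths are required to *reject* motion-blurred spots,
which the assay otherwise overcounts; omitting rotation keeps the fit at 6
parameters and stable in small windows.

**Pixel integration.** By default the model value for a pixel is the
Gaussian integrated over the pixel area (difference of normal CDFs),
rescaled so the amplitude parameter remains the peak of the underlying
continuous Gaussian. This is the exact forward model for a camera pixel;
the classical point-sampled exponential (available via
`pixel_integrated = FALSE`) differs by an effective width inflation of
`σ² → σ² + 1/12 px²`, a ~0.5% bias at the 3.15 px PSF of the confocal
preset — small, but needless, and the integrated model makes noiseless
round-trips exact.

**Initialization and convergence.** Offset from the window-border median;
amplitude as max − offset; position from the background-subtracted
intensity centroid; widths at the expected PSF σ. Levenberg–Marquardt
(minpack.lm) with bounds keeping σ ∈ [0.2, 10×expected] and the center
inside the window. Failures are states, not exceptions: a window with no
signal above background returns `rejected_degenerate`; non-convergence
returns `failed`.

**Disc integration.** Original pixel values (not the model) are summed over
pixels whose *centers* lie within radius `2·√(σx σy)` of the fitted center,
minus offset × pixel count. The center-membership rule is deterministic and
cheap; its pixelation error is well inside the ~2% tolerance implied by the
86% disc correction (`1 − e^{−2} = 0.8647`). Discs clipped by the image
border are flagged `partial_disc`; discs fully outside are errors.

**Quality control.** `status = rejected_blur` when
`max(σx,σy)/min(σx,σy) > 1.3` or `√(σx σy)` falls outside (0.7, 1.6)× the
expected PSF σ. These defaults make explicit a rejection that is otherwise
done by eye. Note the anisotropy gate's sensitivity floor: uniform drift of
length `L` during the exposure adds `L²/12` to one axis's variance, so with
a 3.15 px PSF a drift must exceed ~9 px before the 1.3 ratio trips; slower
drifts are instead caught by the σ band or tolerated.

**Best-focus selection.** With a short Z-stack, each spot is measured on
whichever of the first three frames maximizes its fitted amplitude —
choosing the optimal focal plane while bounding bleaching exposure.

**Conventions.** All coordinates are 0-based `(x, y) = (col, row)` with
pixel centers at integers; every output column carries units in its name
(`intensity_counts`, `fwhm_nm`, `half_life_s`, `D_um2_s`).

## Photobleaching

Traces are per-frame in-ROI means with the camera offset subtracted
*before* normalization (offsets left in place bias the rate downward), then
normalized to the first frame; time runs from the first exposure. The
default fit `I(t) = (1−c) e^{−kt} + c` includes a plateau bounded to
[0, 0.5] absorbing non-bleaching background; since published protocols
often do not state whether an offset term was used, both modes are exposed
and the plateau-free mode is the exactness reference. Initialization: `k`
from a log-linear regression on the first third of the trace, `c` from the
trace minimum. A fit whose total decay over the observation window is under
0.1% is reported `failed` (no measurable decay) rather than returning an
arbitrarily long half-life.

## Tracking and diffusion

**Detection** is local maxima above `median + min_snr × MAD`, refined by a
single-Gaussian fit, with detections closer than one PSF σ merged
(brightest wins) — a deliberate simplification of mixture-model detection
that is accurate for well-separated particles and is validated for
false-positive rate and 0.2 px localization at SNR 10.

**Linking** solves, per consecutive frame pair, the assignment minimizing
total squared displacement with a hard gate (default `5·√(4 D_prior Δt)`
with `D_prior = 1 µm² s⁻¹`, i.e. five times the expected rms frame
displacement). The solver is a Jonker–Volgenant shortest-augmenting-path
implementation on the standard augmented matrix that prices non-linking at
the gate cost, so unmatched detections start new tracks optimally. There is
deliberately no gap closing, merging or splitting: a missed detection ends
the track. Optimality is tested against brute-force permutation
enumeration.

**Track filter.** Lengths strictly greater than 20 and strictly less than
250 frames ("longer than 20, shorter than 250" read literally; both bounds
configurable). At 85 fps the cap keeps tracks under 3 s.

**MSD.** Per track, the time-averaged MSD over all overlapping ordered
pairs at each lag; the per-cell curve averages tracks weighted by pair
count (the standard choice; unweighted track-mean is exposed as an
option). Positions are converted to µm before squaring. **Diffusion fit:**
ordinary least squares over the first `ceil(0.25 × n_lags)` lags (minimum
2), intercept free — static localization error adds a constant positive
MSD offset and exposure averaging a small negative one, and a free
intercept absorbs both without biasing the slope. `D = slope/4`; a negative
slope is reported with a flagged status rather than clipped.

## Comparison statistics

Group comparisons use one-way ANOVA with Tukey–Kramer HSD (studentized
range with unequal-n standard errors, via base R's `TukeyHSD`), validated
two ways: the two-group case reduces to the pooled t-test within 10⁻⁶, and
the family-wise type-I error calibrates to α on null simulations at the
assay's typical design (5 groups × 20 cells). The compact letter display
assigns letters to maximal cliques of the non-significance graph, ordered
alphabetically by group label for deterministic reports.

`fibonacci_spacing()` defines FP spacing as the mean nearest-neighbor 3D
distance among golden-angle lattice points — "spacing" could also mean
lattice-neighbor distance, but nearest-neighbor is the conservative choice
(it is never larger) and is scale-exact (linear in diameter). For 60 points
on a 35 nm sphere it gives 7.48 nm.

`spectral_throughput()` implements the generic overlap computation only:
excitation efficiency as the peak-normalized excitation amplitude at the
laser line, emission capture as the in-band fraction of the unit-area
emission spectrum (trapezoidal), combined throughput as their product. No
specific FP spectra ship with the package.

Emission yields are tagged with a channel label because they are
configuration-specific; comparing yields across channels is only meaningful
at matched irradiance.

## Pipeline provenance

`run_pipeline()` derives every stage's randomness from one master seed and
stamps outputs with the MD5 hash of the canonical-JSON config (output
directory excluded — the same analysis written elsewhere is the same
analysis). Outputs land in `out_dir/<hash>/`, so changing any parameter
produces a fresh directory and never overwrites earlier results. The
pipeline places simulated cages on a jittered grid with guaranteed
separation, emulating the hand-selected isolated particles the spot model
assumes; overlapping spots would inflate intensities and are a known
failure mode of seeded fitting, caught by QC only when the overlap deforms
the shape.

## Problem sizes used in validation

The test suite chooses sizes that make Monte-Carlo tolerances meaningful
at desk scale: ≥10⁵ displacement steps for the step-variance check; 100
noiseless spots for sub-0.01 px localization; 20 noisy movies per half-life
condition (5, 23, 60 s) for 5% half-life recovery; 25 synthetic cells with
≥400 filtered tracks each (at 85 fps, 110 nm pixels) for 10% diffusion
recovery, run at D = 1.0 and 0.5 µm² s⁻¹; 12 noiseless cages per condition
for the 60 vs 120 FP linearity ratio (2.00 ± 0.02); and 1000 null
simulations for Tukey–Kramer calibration. Diffusion recovery feeds
ground-truth trajectories into the filter → MSD → fit chain; the detector
and linker are validated separately on smaller fields, where their
contracts (false-positive rate, localization error, assignment optimality,
identity preservation) can be checked exactly.

## Known limitations

* Seeded spot fitting assumes isolated particles; overlapping spots bias
  intensities upward and are only partially caught by shape QC.
* The linker has no gap closing, so detection dropouts fragment tracks;
  fragment statistics remain unbiased for MSD purposes but track counts are
  not particle counts.
* The anisotropy-based blur rejection is insensitive to drifts below ~3 PSF
  σ per exposure (see above).
* The plateau term and the rate are correlated on short traces; for traces
  much shorter than one half-life, prefer `with_plateau = FALSE` or longer
  acquisitions.
* Emission yield compares FPs within one imaging configuration; the package
  records the channel but cannot validate cross-channel irradiance
  equality.
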