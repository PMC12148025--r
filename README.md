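# nanocagebench

Quantitative benchmarking of fluorescent proteins (FPs) in live cells using
self-assembling protein nanocages.

## The problem

Choosing an FP for live-cell microscopy requires knowing how bright and how
photostable each candidate is *on the imaging system that will actually be
used* — published in-vitro numbers often do not transfer. A 60-subunit
dodecahedral nanocage (~26 nm) tagged with one FP per subunit presents
exactly 60 (or, with tandem tags, 120) FP copies as a single sub-diffraction
particle. The intensity of one nanocage spot is therefore a direct
molecule-by-molecule brightness measurement, independent of expression
level, and the same transfected cells yield photobleaching half-lives and —
because the cages diffuse freely — single-particle tracking statistics.

`nanocagebench` implements the full analysis chain for this assay, plus a
synthetic-microscopy generator that renders ground-truth-annotated image
stacks so every stage can be validated by parameter recovery:

* **synthetic data** — Brownian trajectories (per-axis sub-step displacements
  `~ N(0, 2 D Δt)`), pixel-integrated Gaussian PSF rendering with
  exposure-integrated motion blur, exponential photobleaching, Poisson shot
  noise, Gaussian read noise, camera offset and saturation
  (`simulate_tracks()`, `render_stack()`, `simulate_bleach_movie()`).
* **spot quantification** — sub-pixel elliptical 2D Gaussian fits of seeded
  spots; spot signal integrated inside a disc of radius 2σ around the fitted
  center with the fitted offset (local background) subtracted. The 2σ disc
  holds `1 − e^{−2} ≈ 86%` of a 2D Gaussian's volume
  (`gaussian_disc_fraction()`), which is why per-cell cage counts are
  estimated as `total intensity / cage intensity × 0.86`
  (`fit_spot()`, `integrate_cage_intensity()`, `qc_filter()`,
  `estimate_cage_count()`).
* **photobleaching** — whole-cell ROI traces normalized to the first frame
  and fitted with `I(t) = (1 − c) e^{−kt} + c`; half-life `t½ = ln 2 / k`
  (`roi_mean_trace()`, `fit_decay()`, `compare_half_lives()`).
* **tracking & diffusion** — local-maximum detection with Gaussian
  refinement, frame-to-frame linking by optimal assignment (min total
  squared displacement, hard gate, no gap closing), the 20 < length < 250
  frame track filter, per-cell pair-weighted time-averaged MSD, and
  `D = slope/4` from an ordinary least-squares fit of the initial 25% of the
  MSD curve (`detect_spots()`, `link_tracks()`, `filter_tracks()`,
  `msd_per_cell()`, `fit_diffusion()`).
* **FP comparison** — relative brightness versus a reference FP, the
  relative **emission yield** figure of merit (relative brightness ×
  photobleaching half-life at matched irradiance), one-way ANOVA with
  Tukey–Kramer HSD and compact letter displays, Fibonacci-lattice FP spacing
  on the cage surface, and excitation/emission spectral throughput
  (`relative_brightness()`, `emission_yield()`, `anova_tukey()`,
  `fibonacci_spacing()`, `spectral_throughput()`).
* **pipeline** — TIFF + JSON-sidecar stack I/O, YAML run configs, and
  `run_pipeline()` chaining simulate → quantify → bleach → (track) →
  compare with full seed/config-hash provenance. A thin CLI wrapper lives in
  `inst/scripts/nanocage-bench`.

## Worked example

```r
library(nanocagebench)
optics <- confocal_optics()          # 27 nm px, 200 nm FWHM PSF, 500 ms

## render one 60-FP nanocage (50 photons/s per FP, t1/2 = 60 s) and measure it
cage  <- cage_spec(n_fp = 60, photons_per_fp = 50, bleach_half_life = 60)
tr    <- simulate_tracks(motion_spec(0.001, c(96, 96)), 1, 3, optics, seed = 42)
rend  <- render_stack(simulation_scene(tr, cage, camera_model(), seed = 42))
ft    <- fit_spot(rend$stack[, , 1], round(c(rend$truth$x_px[1], rend$truth$y_px[1])),
                  window = 10, psf_sigma = psf_sigma_px(optics), pixel_size = 27)
integrate_cage_intensity(rend$stack[, , 1], ft)
#> spot_fit [ok]: center (86.401, 61.058) px, sigma (3.322, 3.016) px, amplitude 24.3, offset 99.8
#>   integrated intensity (2-sigma disc): 1318.0 counts
```

The fitted offset (99.8) recovers the camera baseline of 100 counts; the
disc intensity (1318) is the background-corrected cage signal — about 86% of
the ~1496 expected photons at gain 1.

```r
## photobleaching half-life from a whole-cell movie (true t1/2 = 23 s)
movie <- simulate_bleach_movie(c(32, 32), 40, half_life = 23, optics,
                               camera_model(), n_frames = 150, seed = 7)
fit_decay(roi_mean_trace(movie, NULL, optics, camera_offset = 100))
#> bleach_fit [ok] cell1: k = 0.03053 1/s, half-life = 22.7 s, plateau = 0.00353, R^2 = 0.9998

## diffusion coefficient from tracked particles (true D = 1 um^2/s, 85 fps)
tirf  <- tirf_optics()
truth <- simulate_tracks(motion_spec(1.0, c(256, 256), boundary = "periodic"),
                         200, 249, tirf, seed = 1)
trk   <- filter_tracks(tracks_from_truth(truth))
fit_diffusion(msd_per_cell(trk, tirf))
#> diffusion_estimate [ok]: D = 0.9796 um^2/s (slope 3.919, intercept -0.0108 um^2, 62 lags fitted)

## geometry: are 60 FPs on a ~35 nm sphere far enough apart to avoid quenching?
fibonacci_spacing(60, 35)
#> [1] 7.48433
```

7.5 nm mean nearest-neighbor spacing is comfortably above the <5 nm range
where FP self-quenching becomes noticeable.

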