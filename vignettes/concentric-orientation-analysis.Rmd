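---
title: "Analysing concentric orientation organization in the superior colliculus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing concentric orientation organization in the superior colliculus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collimap)
```

## The scientific problem

The superficial superior colliculus (sSC) of the mouse is retinotopically
organized, and its neurons are often orientation selective. `collimap`
implements the analysis chain used to establish two organizational claims
about this structure and to test them quantitatively:

1. **Columnar organization**: units recorded at different depths along a
   penetration perpendicular to the tectal surface prefer the same grating
   orientation. The statistic is the median, over penetrations, of the axial
   circular variance of unit preferences, tested against a null distribution
   obtained by reshuffling all preferences over all recording positions.
2. **Concentric organization**: the preferred orientation at each retinotopic
   location is the orientation tangent to the circle around the centre of
   vision through that location (equivalently, perpendicular to the radial
   line from the nose axis). This is tested by building, purely from the
   measured retinotopy and the screen geometry, a predicted
   concentric-orientation map and correlating it with the measured
   orientation-preference map.

Both claims are exercised end to end on synthetic data with known ground
truth, because the package must be verifiable without any recordings.

## Axial statistics

Orientations live on a 180°-periodic axis and are analysed by angle
doubling. For preferences $\phi_p$ on one penetration:

* circular mean: $\tfrac12 \arg \sum_p e^{2i\phi_p}$,
* circular variance: $1 - \bigl|\sum_p e^{2i\phi_p}\bigr|/n \in [0,1]$,

with the convention that a penetration whose doubled angles balance exactly
(e.g. two orthogonal preferences) has variance 1 and an undefined mean. The
columnar test reshuffles the pooled preferences over the original
penetration-size partition (`shuffle_columnar_test()`); its p-value uses the
add-one estimator $(1 + \#\{\text{null} \le \text{real}\})/(1 + N)$ so that
p is never zero. The pooled vector and the size partition are put in a
canonical sorted order before the permutations are drawn, which makes the
p-value exactly invariant to how penetrations and units were ordered in the
input.

Circular–circular association uses the Fisher–Lee coefficient on doubled
angles, computed through the $O(n)$ resultant identity and verified in the
tests against a brute-force transcription of the pairwise-sine formula. One
property of this coefficient matters later: it is invariant under a global
rotation of either angle set.

## From fluorescence to maps

The stimulus-triggered response of a pixel is
$(R_s - R_0)/R_0$, where $R_s$ averages the intensity from 0.3 s after
stimulus onset to 2 s after offset, and $R_0$ from 3 s before onset to
0.3 s after onset. Two numerical choices deserve a note:

* **Window weighting.** At a 1.8 Hz frame rate the window edges never
  coincide with frame boundaries. Selecting frames by a membership rule
  (e.g. frame midpoint inside the window) makes the windowed mean depend on
  the phase of the stimulus onset relative to the frame clock; that phase
  error is *identical for every pixel*, so across conditions it acts as a
  small global response difference. For well-tuned pixels it is negligible,
  but for untuned pixels it aligns the noise-driven preferred angles of the
  whole map, which inflates the variance of any map-level correlation under
  the null. Frames are therefore weighted by the fraction of their exposure
  interval inside the window: the windowed mean is then the exact time
  average of the frame-wise-constant trace and has no phase sensitivity.
* **Reference correction.** Responses are divided by one plus the response
  of a visually non-responsive reference region, correcting slow
  fluorescence changes unrelated to activity. If no reference region is
  supplied the correction is skipped and noted.

Maps are smoothed with a mask-aware Gaussian (default $\sigma$ = 33 µm,
3 pixels at 11.04 µm/pixel). Orientation (axial) maps are smoothed in the
complex domain — convolve $A\,e^{2i\theta}$, retake half-angle and modulus —
so there is no wrap artifact at the 0°/180° boundary.

Per-pixel products are:

* **retinotopy** (`retinotopy_argmax_map()`): the monitor patch evoking the
  largest trial-mean response, ties to the lowest patch id;
* **orientation preference** (`orientation_polar_map()`): for each grating
  orientation the larger of the two opposing-direction responses (clamped at
  0), then the half-argument of $\sum_\phi R(\phi)e^{2i\phi}$. Drift
  directions convert to grating orientations as
  $(\text{direction}+90) \bmod 180$, so upward-drifting gratings are
  horizontal;
* **significance** (`anova_significance_map()`): one-way ANOVA of per-trial
  responses across the four orientations (opposing directions pooled),
  vectorised over pixels and cross-checked against `anova(lm())`;
* **single-condition maps**: mean over a direction subset minus the mean
  over all directions; over any equal-size partition these sum to zero.

## Geometry and the concentric prediction

Patch-wise response maps are fitted with an elliptical 2D Gaussian after
subtracting a 0.1% (ΔF/F) pedestal and flooring at zero; patches whose
fitted peak response is below 0.4% are excluded. The included centres are
triangulated (Bowyer–Watson) in pixel space and each pixel inside the convex
hull gets piecewise-linearly interpolated monitor coordinates, which are
mapped to head-centred coordinates ($z$ along the body axis, $x$ right, $y$
up; head pitch applied before roll) and then to visual angles:
$\mathrm{azimuth} = \arctan(x/z)$,
$\mathrm{elevation} = \arctan\!\bigl(y/\sqrt{x^2+z^2}\bigr)$.

The concentric angle at $(x, y)$ is $(90° - \operatorname{atan2}(y,x))
\bmod 180°$: vertical (90°) on the temporal horizontal axis, horizontal (0°)
directly above the nose, scale-invariant along rays and symmetric under
point reflection. Pixels representing the nasal ipsilateral hemifield
(azimuth < 0 for a right-hemisphere preparation) are assigned the horizontal
orientation. The predicted map is finally smoothed with a 132 µm axial
Gaussian, which stands in for receptive-field position scatter and light
scatter in the optics.

When head pitch and roll were not recorded, `fit_head_angles()` grid-searches
them by rebuilding the prediction under each candidate. The objective is the
mean angular agreement $\overline{\cos 2(\theta_{meas}-\theta_{pred})}$
rather than the circular correlation: a roll rotates the whole predicted
field by a constant, and the Fisher–Lee coefficient is exactly invariant
under such rotations, so roll would be unidentifiable by correlation (the
profile is verifiably flat). Agreement is rotation-sensitive and peaks at
the generating angles in the recovery tests.

## Comparison statistics

`compare_orientation_to_concentric()` correlates measured and predicted
orientations over pixels passing both masks and a minimum-response filter
(default: every condition's mean response ≥ 0.5% ΔF/F — the strict reading;
an any-condition switch exists), and histograms the signed axial differences
in 18 bins of 10° spanning [−90°, 90°]. Because the coefficient's null
distribution depends on the spatial correlation of the maps, a permutation
p-value (pixel pairings shuffled) accompanies it. For electrode data,
`penetration_concentric_test()` compares each penetration's circular-mean
preference with the concentric angle at its receptive field; when all
receptive fields lie on one radial line the predictor is constant and the
correlation is flagged degenerate rather than reported.

## The synthetic generator

`gen_imaging_dataset()` emulates the imaging preparation: an axis-aligned
affine retinotopy from the image onto the monitor; per-pixel orientation
tuning $dc + \exp(\cos 2(\phi - \phi_{pref}) - 1)$ centred on the rule's
angle (`concentric`, `random_smooth`, or `uniform_null` = untuned);
responses blurred by an optical/retinotopic scatter kernel (default 132 µm
— precisely the blur the concentric-map smoothing is meant to emulate; a
generator without it would make that smoothing a modelling error); a
saturating-rise, exponential-decay indicator kernel (τ = 1.5 s,
GCaMP6s-like); multiplicative slow drift (1% sinusoid with 300 s period
plus a 1% linear trend); Gaussian frame noise (1% of baseline
fluorescence); and an optional non-responsive corner region for the
reference correction. Stimuli follow the standard design: 3 s duration,
9 s interstimulus interval, randomized patch block (4 × 4 grid) and grating
block (8 directions). The default monitor geometry (29.5 cm distance,
centre offset (40, 10) cm) places the represented field in the
contralateral hemifield with a small nasal ipsilateral rim, matching the
recorded preparations.

`gen_ephys_dataset()` draws a receptive field per penetration, a centre
orientation per the columnar rule (concentric at the receptive field,
random, or no columnar structure), unit preferences from an axial von Mises
(Best–Fisher sampling) around the centre, and Poisson trial rates from a
fixed-concentration von Mises tuning curve over 16 drift directions.

What the generator does **not** emulate: haemodynamic contamination,
vascular artifacts, eye movements, non-affine retinotopic distortion,
correlated (non-Poisson) spiking, and electrode drift. Passing tests
therefore validate the analysis logic and its statistical calibration, not
robustness to every artifact of real recordings.

## Problem sizes and defaults

The verification runs use a 96 × 96 pixel image with 10 grating repetitions
× 8 directions and 5 patch repetitions × 16 patches (about 3,500 frames),
and ephys ensembles of 20 penetrations × 8 units with 5 trials × 16
directions; shuffle-test calibration uses 500 null and 200 columnar
replicate ensembles at 2,000 shuffles each. These sizes give stable
statistics while keeping a full verification run in minutes on one core.
Production analyses default to 10,000 shuffles.

All tunable parameters live in `default_config()` with their standard
values (33 µm and 132 µm smoothing, 0.1% pedestal, 0.4% patch inclusion,
0.5% minimum mean response, 2 Hz unit inclusion, α = 0.05, 29.5 cm monitor
distance, 1.8 Hz, 11.04 µm/pixel, 3 s stimulus, 9 s minimum ISI) and can be
overridden from YAML via `load_config()`.

## Known limitations

* The map-level circular correlation is a wide-variance statistic whenever
  the measured map carries spatially shared noise; its permutation p-value
  is the robust indicator of association and should be reported alongside.
* The concentric angle is undefined at the centre of vision and unstable
  near it; preparations whose represented field includes the origin will
  show localized disagreement there regardless of the underlying biology.
* Roll recovery in `fit_head_angles()` relies on rotation-sensitive
  agreement; if the represented field is rotationally featureless (no
  ipsilateral rim, no hull anisotropy) roll remains weakly constrained.
* The 2D Gaussian patch fit has no orientation (covariance) term; strongly
  sheared retinotopies would need it.

## A minimal worked example

```{r example, eval = FALSE}
ds <- gen_imaging_dataset(dim = c(64, 64), reps_grating = 5, reps_patch = 3,
                          seed = 1)
res <- run_imaging_pipeline(ds$stack, ds$schedule,
                            geom = ds$ground_truth$geom,
                            reference_roi = ds$ground_truth$reference_roi,
                            out_dir = "artifacts")
res$comparison

ep <- gen_ephys_dataset(rule = "columnar_concentric", seed = 1)
eres <- run_ephys_pipeline(ep$trials,
                           rf_table = ep$ground_truth$penetrations[
                             c("penetration_id", "rf_azimuth_deg",
                               "rf_elevation_deg")])
eres$columnar$shuffle
eres$concentric$circ_corr
```
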