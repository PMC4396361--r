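# collimap

Analysis of the functional organization of orientation preference in the
superficial superior colliculus (sSC), for the two modalities in which it is
measured: extracellular recordings along electrode penetrations and
wide-field calcium imaging of the collicular surface.

## The science

Neurons in the mouse sSC are orientation selective, and their preferences
are organized in two striking ways:

* **Columnar**: units along a penetration perpendicular to the tectal
  surface share a preferred orientation. With preferences
  $\phi_p \in [0°, 180°)$ at recording positions $p$, each penetration gets
  a circular mean $\tfrac12\arg\sum_p e^{2i\phi_p}$ and circular variance
  $1-|\sum_p e^{2i\phi_p}|/n$; the median variance over penetrations is
  compared with the distribution obtained by reshuffling all preferences
  over all positions (10,000×), giving a permutation p-value for clustering.
* **Concentric**: the preferred orientation at each retinotopic position is
  tangent to the circle around the centre of vision through the receptive
  field — $(90° - \operatorname{atan2}(y, x)) \bmod 180°$ in head-centred
  coordinates, with the nasal ipsilateral field assigned horizontal. The
  package builds this prediction purely from measured retinotopy (2D
  Gaussian patch fits → Delaunay interpolation → azimuth/elevation) and
  correlates it with the measured orientation map (Fisher–Lee circular
  correlation on doubled angles).

Supporting machinery: stimulus-triggered ΔF/F with reference-region
correction, mask-aware Gaussian map smoothing (axial maps smoothed in the
complex domain), orientation/direction selectivity indices (OI, DSI), von
Mises tuning fits, per-pixel ANOVA significance maps, single-condition
maps, and a synthetic-data generator for both modalities with known ground
truth. See the methods vignette
(`vignettes/concentric-orientation-analysis.Rmd`) for models, parameters
and numerical choices.

## Worked example

```r
library(collimap)

## imaging: generate a synthetic session with concentric ground truth,
## run the full map pipeline, compare measured vs predicted orientation
ds  <- gen_imaging_dataset(dim = c(64, 64), reps_grating = 5,
                           reps_patch = 3, seed = 1)
res <- run_imaging_pipeline(ds$stack, ds$schedule,
                            geom = ds$ground_truth$geom,
                            reference_roi = ds$ground_truth$reference_roi)
res$comparison
#> Orientation map vs concentric prediction
#>   qualifying pixels: 1566
#>   circular correlation: 0.988  (permutation p = 0.000999)
#>   median |angle difference|: 2.4 deg

## electrophysiology: columnar statistics and the penetration-level test
ep   <- gen_ephys_dataset(rule = "columnar_concentric", seed = 1)
eres <- run_ephys_pipeline(ep$trials,
          rf_table = ep$ground_truth$penetrations[
            c("penetration_id", "rf_azimuth_deg", "rf_elevation_deg")])
eres$columnar$shuffle
#> Columnar shuffle test
#>   real median circular variance: 0.0722
#>   null median (of 10000 shuffles):  0.2684
#>   p-value: 9.999e-05
eres$concentric$circ_corr
#> [1] 0.969
```

Reading the numbers: the measured orientation map agrees with the purely
geometric concentric prediction (correlation 0.99 over 1,566 pixels passing
the mask and minimum-response filter, with a typical angular error of ~2°);
the real median circular variance (0.07) lies far below every shuffled
median, so unit preferences cluster along penetrations far more than chance
allows; and the penetration-level circular means track the concentric angle
at their receptive fields (correlation 0.97).

A thin command-line wrapper with subcommands `simulate`, `imaging-maps`,
`ephys-columnar` and `concentric-compare` lives at
`inst/scripts/collimap.R`.

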