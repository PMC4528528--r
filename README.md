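# shoalwatch

Spatial occupancy and predator-inspection analysis for tracked fish shoals
in arena assays.

## What it is for

Behavioural ecologists film small fish shoals (1-4 unidentified individuals)
from above in a 59 x 29 cm tank while a stimulus object — a predator model or
a neutral novel-object control — stands at one end, typically 20 minutes per
trial at 30 frames/s. Because identities cannot be maintained, the shoal is
the sampling unit: every trial contributes one value to every statistic.
`shoalwatch` takes tracked coordinates and scored inspection events from
there to publication-grade summaries:

* **Geometry** — projective rectification of obliquely filmed coordinates
  onto the arena plane (`fit_homography()`, `rectify_trajectory()`), rigid
  overlay of the stimulus object across trials (`align_trajectory()`), and
  the missing-data policy for unreliable tank regions
  (`mask_trajectory()`).
* **Occupancy heat maps** — per-trial 0.5 cm grid density maps
  (`density_map()`) and three cell-wise non-parametric maps: occupancy
  against each trial's median cell density by Pratt signed-rank
  (`occupancy_significance()`), group comparison by rank-sum
  (`compare_groups()`), and replicate combination by unweighted Stouffer's z
  (`stratified_combine()`), each with a separate direction channel. For a
  cell-wise two-sided p and direction d, replicates combine as

  z_r = d_r * Phi^-1(1 - p_r / 2),  Z = sum(z_r) / sqrt(k),
  p = 2 * (1 - Phi(|Z|)).

* **Distance profiles** — distance-to-object densities per trial
  (`distance_series()`, `distance_density()`), a Monte Carlo uniform-arena
  null (`uniform_null_density()`), and relative profiles with
  trial-resampling bootstrap bands (`relative_distance_profile()`).
* **Inspection responses** — per-trial behavioural variables from scored
  event logs (`summarize_inspections()`, `pooled_rate()`), response
  transforms, the average-speed activity metric, and crossed-design
  arithmetic (`enumerate_design()`).
* **Models** — declarative mixed-model candidate sets per response
  (`candidate_specs()`), fitting delegated to lme4/lmerTest, and the
  delta-AIC > 2 term-retention rule (`select_by_delta_aic()`).
* **Synthetic studies** — an agent-based generator (`simulate_trial()`,
  `simulate_study()`, `apply_camera()`) producing trajectories, event logs
  and manifests with known ground truth: avoidance ring at a set radius,
  Poisson inspection bouts with attack-cone avoidance, freezing, shoal
  cohesion, perspective distortion and occlusions.

Results are tibbles; `autoplot()` methods render the heat maps (nonlinear
signed p scale, diverging palettes per test family) and profile ribbons;
fitted models have `tidy()` and `glance()` methods.

## A worked example

Simulate twelve predator trials, map their occupancy, and recover the
avoidance ring the generator planted at 10 cm:

```r
library(shoalwatch)

pose <- object_pose(12, 14.5, 90)            # predator model, arena frame
trials <- lapply(1:12, function(i)
  simulate_trial(pose = pose, shoal_size = 4, seed = 700 + i))
maps <- lapply(trials, function(t) density_map(t$trajectory))

sig <- occupancy_significance(maps)          # Pratt signed-rank per cell
estimate_ring_distance(sig, pose)
#> [1] 9.75

bins <- distance_bins(1)
null <- uniform_null_density(pose = pose, bins = bins,
                             n_samples = 2e5, seed = 1)
pt <- lapply(trials, function(t)
  distance_density(distance_series(t$trajectory, pose), bins))
prof <- relative_distance_profile(pt, null, n_boot = 1000, seed = 2)
profile_peak(prof)
#> [1] 9.5

summarize_inspections(trials[[1]]$events, shoal_size = 4)
#> # A tibble: 1 x 5
#>   n_inspections mean_duration_s time_per_fish_s occurred rate_per_hour
#>           <int>           <dbl>           <dbl> <lgl>            <dbl>
#> 1            12            5.30            33.9 TRUE                36
```

The ring estimate (9.75 cm) is the distance bin with the highest fraction of
significantly over-visited cells — within one 0.5 cm grid cell of the
generator's 10 cm radius — and the relative distance profile peaks at
9.5 cm: the shoals concentrated about 10 cm from the model, well above what
uniform use of the tank would produce. The inspection summary shows the
per-trial response variables that feed the mixed models (here 12 bouts of
5.3 s on average, 36/h, with 33.9 s of inspection person-time per fish in
the first simulated trial; `autoplot(sig)` and `autoplot(prof)` draw the
corresponding heat map and profile).

## Package layout

| Area | Files |
| --- | --- |
| Geometry and masking | `R/arena.R`, `R/geometry.R` |
| Occupancy grids and cell-wise tests | `R/occupancy.R`, `src/shoalwatch.cpp` |
| Distance profiles and null | `R/distances.R` |
| Inspection responses and design | `R/inspections.R` |
| Model specs and delta-AIC selection | `R/models.R` |
| Synthetic generator and camera | `R/simulate.R`, `R/camera.R`, `src/shoalwatch.cpp` |
| I/O (CSV trajectories/events, YAML manifests, map export) | `R/io.R` |
| Plots and tidiers | `R/plots.R`, `R/models.R` |

The methods vignette (`vignettes/shoalwatch-methods.Rmd`) documents the
statistical choices, the generator's assumptions, and known limitations.
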