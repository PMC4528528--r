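---
title: "Methods: spatial occupancy and inspection analysis for arena assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial occupancy and inspection analysis for arena assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Predator-response assays on small fish shoals are filmed from above: a
stimulus object (a painted predator model, or a neutral novel object as a
control) is placed at one end of a 59 x 29 cm tank and the positions of 1-4
unidentified fish are tracked for 20 minutes at 30 frames/s. Because
individual identities cannot be maintained, every measurement is treated as a
property of the *shoal*, which is the sampling unit throughout: one value per
trial enters every statistic. `shoalwatch` implements the full analysis chain
from tracked coordinates to statistical heat maps, distance profiles, and
per-trial behavioural response tables, plus an agent-based generator of
synthetic trials so the whole chain can be exercised and calibrated without
any video data.

# Geometry: one common frame for all trials

Tanks are filmed at a slight angle, so raw coordinates live in a camera plane.
`fit_homography()` estimates the 3 x 3 projective transform from corner
correspondences (exact direct linear solution at 4 points, least squares with
more, Hartley normalisation for conditioning) and `rectify_trajectory()` maps
detections onto the arena plane. The arena frame is fixed as: origin at the
corner nearest the stimulus end, x along the 59 cm axis, y along the 29 cm
axis, continuous centimetre coordinates. No source material dictates a frame;
one must be fixed for grid cells to be comparable across trials, and this is
the choice recorded here.

Because the object is placed by hand, its pose varies slightly between
trials. `align_trajectory()` applies the rigid motion (translation plus
rotation) that carries each trial's measured pose onto a common reference
pose, so positions become relative to the object rather than the tank.
The default reference is the component-wise mean pose over the trials at hand
(`reference_pose()`), which minimises average displacement; any fixed pose
can be supplied instead. When a heading is unavailable the rotation is
skipped with a warning rather than guessed. Points carried outside the
nominal arena by the overlay are retained and flagged (`in_arena`); they stay
valid but fall outside every grid cell, so they reduce no denominator
silently.

Two tank regions are unreliable in this kind of data: under a glass ledge at
one short edge (roughly a tenth of observations in the emulated studies) and
directly over the object, where fish are not distinguishable from it.
`mask_trajectory()` implements the missing-data policy: ledge-type regions
clear the validity flag; over-object regions keep a dedicated `at_object`
flag so those observations still enter distance profiles in the lowest bin
(the fish is known to be at the object even though its coordinates are not
usable).

# Occupancy maps and cell-wise tests

`density_map()` bins each trial's valid observations into half-open
0.5 x 0.5 cm cells; each observation contributes 1/n, so the map is the
fraction of observations per cell and sums to exactly 1. One map per trial:
each trial contributes a single value to every cell-wise test.

Cell densities are heavily zero-inflated (shoals never visit most cells) with
occasional extreme values (freezing can park a shoal on a few cells for
minutes), so parametric per-cell models would be fragile. Three
non-parametric maps are provided:

* **Occupancy vs baseline** (`occupancy_significance()`): per cell, a
  two-sided Wilcoxon signed-rank test of the trial densities against each
  trial's own *median cell density*. Pairing within trial is the reading
  adopted for "compare densities to the median density": it respects the
  one-value-per-trial principle; a pooled grand-median baseline is available
  as an option. Zero differences are handled by the Pratt convention (zeros
  ranked, then dropped) precisely because all-zero cells are the norm. Cells
  where every difference is zero are reported as undefined, not significant.
* **Group comparison** (`compare_groups()`): per cell, a two-sided Wilcoxon
  rank-sum test between two groups of trials, with direction
  `sign(median_A - median_B)` carried separately (direction is read from
  colour in the heat maps; the tests themselves are two-sided).
* **Replicate combination** (`stratified_combine()`): the replicate selection
  lines are genetically independent, so each replicate's comparison is
  treated as an independent experiment and combined per cell with
  unweighted Stouffer's z: `z_r = direction_r * qnorm(1 - p_r / 2)`,
  `Z = sum(z_r) / sqrt(k)`. Cells undefined in some replicates are combined
  over the defined subset, with the effective k recorded.

Exactness policy for the rank-sum: the exact null (via `pwilcox`) when the
combined sample is at most 25 trials with no ties; full enumeration of group
assignments with midranks when ties are present but the combined sample is
small (at most 16, where enumeration is cheap); otherwise the normal
approximation with tie and continuity corrections. The per-cell choice is
recorded in the map's `method` column. The signed-rank test enumerates all
sign assignments exactly whenever at most 16 non-zero differences remain,
which covers every realistic per-cell sample in this design.

No multiple-testing correction is applied by default. Neighbouring cells are
positively correlated (a fish reaches a cell through its neighbours) and the
sum-to-one constraint induces negative correlation at range, which partly
offsets the multiplicity problem; the maps are read for large-scale patterns
(rings, halves of the tank), never for single cells. A Benjamini-Hochberg
option exists for users who want it.

`time_windows()` splits trials into consecutive windows (e.g. four 5-minute
periods) for time-resolved versions of all maps.

# Distance profiles against a uniform-arena null

`distance_series()` measures the Euclidean distance of every usable
observation to the object centroid (distance to the nearest footprint point
is available as an option; the centroid is the default reference because the
emulated studies report only "distance to the predator"). At-object
observations contribute distance 0. `distance_density()` bins distances into
1 cm half-open bins (bin width configurable; no bin width is dictated by the
source material).

Raw distance densities are dominated by geometry: even uniformly placed fish
show a rising-then-falling distance density because annulus area grows with
distance until the tank walls cut it off. `uniform_null_density()` therefore
estimates, by Monte Carlo, the distance density of points uniform over the
arena footprint *minus the object footprint* (fish cannot occupy the object's
area; the pure rectangle is available as an option), and
`relative_distance_profile()` subtracts it per trial. The Monte Carlo route
was chosen because rectangle-minus-capsule geometry has no convenient closed
form; the circular-arena closed form (annulus density `2r/R^2`) is used as a
test oracle only. The group curve is the element-wise median across trials,
with a percentile-bootstrap 95% band obtained by resampling trials (the
sampling unit) with replacement, 1000 resamples by default.

The band is pointwise. Its calibration is checked per bin: with trials drawn
i.i.d. from a continuous generator with a known median curve, each bin's band
covers the truth in at least 90% of seeded repetitions. Joint coverage across
all bins simultaneously is not a property a pointwise 95% band can promise
(it decays roughly like `0.95^k` in the number of bins), so it is not
asserted.

# Inspection responses and models

`summarize_inspections()` turns manually scored event logs (start, end,
inspecting-group size) into the per-trial responses: count, mean duration,
time spent inspecting per fish, occurrence, hourly rate. "Time per fish" is
person-time — each event contributes duration x group size, divided by shoal
size — because group size is recorded per event; union-time (time during
which at least one fish inspected) is available as an option. Overlapping
events are legal and never merged. `pooled_rate()` reproduces the headline
inspections-per-hour arithmetic with integer rounding for reporting.

Model specifications mirror the standard analysis: for each gaussian
response (log-transformed count and mean duration, power-transformed time
per fish; the power exponent is not dictated by the source material and
defaults to 0.5, recorded in every output), the candidate set is
`brain size x shoal size`, the two mains, and brain size alone — brain size
and the per-replicate random intercept + brain-size slope appear in every
candidate. Occurrence is a single binomial specification with a treatment
fixed effect and random intercepts for replicate and shoal identity.
`select_by_delta_aic()` walks the candidates from most to least complex and
keeps extra complexity only when it improves AIC by more than 2. AICs are
compared under ML (`REML = FALSE`) because REML likelihoods of different
fixed-effect structures are not comparable; REML is available as an option.
Fitting itself is delegated to `lme4`/`lmerTest` (Satterthwaite denominator
degrees of freedom); this package asserts structural properties of fits, not
the engine's numerics.

# The synthetic-data generator

`simulate_trial()` produces ground-truth trajectories and event logs from a
deliberately simple kinematic model: overdamped steering in polar coordinates
around the object. The distance to the object relaxes toward the preferred
ring radius as a discrete Ornstein-Uhlenbeck process whose stationary sd is
the `ring_tightness_cm` parameter (relaxation time 5 s), while the angular
coordinate advances at roughly cruise speed with rare direction reversals;
cohesion pulls a straggler toward the rest of the shoal in polar coordinates
(mean ring distance of the others, mean direction), which keeps grouping from
biasing the ring radius inward the way a naive centroid pull does. Inspection
bouts arrive as a Poisson process; a uniformly drawn subgroup swims straight
to a target drawn at the approach distance on the object's flank or rear
(head cone with small probability, reflecting attack-cone avoidance) and
resumes ring behaviour when the bout ends. Freezes arrive with a per-minute
hazard and suspend motion for a capped exponential duration. All positions
are constrained inside the arena and outside the object footprint.

This is a test harness, not a model of guppy locomotion: it produces the
phenomena the pipeline must detect (an avoidance ring at a known radius,
saltatory inspection bouts at a known rate, freezing, shoal cohesion,
camera distortion and occlusion-induced missing data) with known ground
truth. Default magnitudes are the study conditions being emulated: 20-minute
trials at 30 frames/s, a 10 cm ring, inspection rates of 23/h overall and
32/h for shoals of four, freezes up to several minutes, a 12 x 3 cm capsule
footprint for the model. Parameters with no stated magnitude (cruise speed
8 cm/s, ring sd 2 cm, bout duration 5 +/- 2 s, approach 5 cm, cohesion range
8 cm, freeze hazard 0.02/min) were fixed once at values a fish-behaviour
practitioner would call unremarkable, and are recorded in every ground-truth
manifest. What passing recovery tests shows is that the *pipeline* is
correct and calibrated, not that real guppies move like the generator; in
particular the generator has no wall-following, thigmotaxis, or
stimulus-habituation dynamics, so time-window analyses on synthetic data are
stationary by construction.

One deliberate deviation from a literal reading of the module plan: per-trial
stimulus-pose jitter is drawn when the trial is generated (so the fish
actually behave relative to the jittered pose) rather than applied as an
afterthought to the recorded pose by the camera stage, which would make the
recorded pose inconsistent with the trajectory around it. The camera stage
(`apply_camera()`) handles what acquisition does: perspective distortion
through the inverse rectifying homography, deletion of ledge-occluded
observations, at-object bookkeeping for fish over the object, and emission of
exactly the corner correspondences needed to undo the distortion.

The default stimulus reference pose sits 12 cm from the stimulus-end wall on
the midline. With a 10 cm avoidance ring this leaves the full ring inside the
arena; an object nearer the wall clips the ring and biases ring-distance
estimates inward, which is a property of the geometry, not of the estimator.

# Numerical choices and degenerate inputs

* Homography fitting refuses configurations with three collinear source
  points and normalises the result to a unit bottom-right coefficient;
  points mapped to the line at infinity are flagged invalid, never fatal.
* Density maps refuse trials with zero valid in-grid observations (an
  empty-trial error) rather than emitting NaNs.
* Signed-rank cells where every difference is zero, rank-sum cells with zero
  variance, and Stouffer cells undefined in every replicate are reported
  undefined (`p = NA`, direction 0).
* `estimate_ring_distance()` summarises a significance map by the distance
  bin holding the highest *fraction* of significant cells (ties broken by
  their median distance), not the highest count: annuli grow linearly with
  distance, so a count-based mode would be biased outward by geometry alone.
  Nearly empty annuli (under 3 cells) are ignored.
* Detection of a planted group contrast in the combined map is declared when
  more than 5% of defined near-object cells (within 12 cm) are significant
  at 0.05 in the planted direction — double the 2.5% a null map would show
  in one direction.
* All simulation, Monte Carlo and bootstrap entry points take explicit seeds
  and are bit-reproducible; study-level seeds are derived deterministically
  from one base seed.

# Problem sizes used in the shipped checks

The test suite and acceptance script run the generator at the emulated study
scale where it matters (20-minute trials at 30 frames/s on the 0.5 cm grid
for ring recovery; 12 trials per group and 3 replicate lines for the planted
contrast, 50 replicate studies in the test suite and 20 in the acceptance
script's summary) and at reduced scale for unit tests of plumbing, where a
few seconds of trajectory exercise the same code paths. Type-I calibration
uses 10,000 independent synthetic cells per test family; the Monte Carlo
null check uses 10^6 draws against the closed-form annulus density.

# Known limitations

* The per-cell tests ignore spatial autocorrelation between cells; the maps
  are descriptive instruments for large-scale patterns, and no
  family-wise error control is attempted by default (by design).
* Greedy nearest-neighbour matching in `average_speed()` is plumbing for
  unidentified detections, not a tracking algorithm; it discards plausible
  matches beyond the jump threshold (default 5 cm/frame) and will
  underestimate speed during identity-swap-dense episodes.
* The rank-sum normal approximation is used for tied cells beyond combined
  n = 16; at the design's 12 + 12 trials per comparison this affects only
  tied (mostly rarely-visited) cells.
* The generator's behavioural realism is intentionally minimal (no
  habituation, no wall preference, no inter-individual variation), so
  synthetic effect sizes translate to real data only qualitatively.
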