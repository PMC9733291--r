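---
title: "Classifying time-activity-location patterns from personal monitor traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying time-activity-location patterns from personal monitor traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timeactivity)
```

## The problem

Personal exposure to air pollution depends strongly on *where* a person is
and *what* they are doing: concentrations and inhalation rates differ by an
order of magnitude between a bedroom at night, a kitchen at dinner time, a
busy road on a bicycle and a metro carriage. Exposure studies therefore need
each minute of a participant's week assigned to a microenvironment — home,
work or other static locations, each indoor or outdoor, sleep, or one of
five transport modes (walking, cycling, car, bus, train/metro). Manual
activity diaries are laborious and error-prone; this package classifies
those patterns automatically from the channels a wearable monitor (or a
smartphone) already records: GPS position and satellite count,
accelerometry, microphone level, docking state, and optionally a
coarse-particle (PM10) channel.

The classifier is a composite of rule-based steps and machine-learning
steps, applied per participant in six stages.

## The six steps

**Step 1 — home.** People are usually at home in the small hours. Minutes
where the unit is docked in its charging base station, the local clock is in
the night window (default [02:00, 04:00), half-open, configurable for shift
workers), and the GPS fix is valid are pooled across all nights. A k-means
split with k = 2 decides whether these fixes form a single cluster: they do
if the two centres are closer than `sep_min_m` (300 m) or the minor cluster
holds under `minor_frac` (10%) of the points (in which case the minor
cluster is treated as outlier noise). A single cluster yields an elliptical
buffer zone — centroid plus per-axis spread distances — and every valid fix
inside the ellipse is labelled home. Multiple clusters (sleeping in several
places) or fewer than `min_night_points` (30) usable fixes leave home
undetermined, to be recovered in Step 3.

The spread per axis is 2.45 × the MAD-based robust SD, the radius that
encloses 95% of an isotropic bivariate normal scatter. A smaller multiplier
(e.g. 2σ, ~86% coverage) leaks a visible fraction of genuine home minutes
out of the zone; the robust scale keeps single-fix GPS excursions from
inflating it. Spreads are clamped to [60, 500] m, the plausible range for
building-scale GPS scatter; the floor also covers near-degenerate scatter.

**Step 2 — static clusters vs directional movement.** The remaining valid
fixes are analysed with time-scaled-distance (TSD) local convex hulls, a
home-range technique from movement ecology. The TSD between two fixes is

\[ d = \sqrt{\Delta x^2 + \Delta y^2 + (s\, v\, \Delta t)^2} \]

with \(s\) a dimensionless scaling (default 0.05), \(v\) the participant's
characteristic velocity (median positive inter-minute speed) and
\(\Delta t\) in seconds. This is the simplest symmetric form that reduces to
the Euclidean distance at \(\Delta t = 0\) or \(s = 0\) and penalises pairs
far apart in time, making hulls local in space *and* time. Coordinates are
first converted to a conformal UTM projection (zone fixed from the trace
centroid; at city scale the distortion from straddling a zone boundary is
negligible).

Around each parent point, neighbours sorted by TSD are accumulated while
their cumulative TSD stays within an adaptive radius *a*, so dense areas get
more neighbours than sparse ones. The radius is chosen automatically as the
smallest value for which the median neighbourhood reaches
`a_target_neighbors` (10) points; this is computed exactly as the median
over parents of the cumulative TSD of each parent's 10 nearest neighbours
(the closed-form limit of a bisection on the radius). Parent plus neighbours
are bound into a minimum convex polygon. Hull shape separates behaviour:
the eccentricity of the bounding ellipse, \(\sqrt{1-\lambda_2/\lambda_1}\)
from the member covariance eigenvalues, is near 0 for a stationary scatter
and near 1 for points strung along a movement path; degenerate (collinear or
singleton) hulls carry eccentricity 1 and an infinite perimeter-area ratio
by convention. A minute is *in movement* iff its hull eccentricity reaches
the participant's 75th-percentile eccentricity **and** its density (member
count) is at most the participant's median density; thresholds are
per-participant quantiles because absolute hull geometry varies with GPS
quality and mobility style. Hulls can also be merged into isopleths —
accumulated by density or eccentricity until 95% of points are enclosed —
for inspection and export.

**Step 3 — roles of static clusters.** Static minutes are grouped by
density-based spatial clustering (eps 150 m, minimum 10 minutes). Each
cluster gets visit metrics with a 12-hour inter-visit gap, capturing diurnal
revisitation: `nsv` (number of separate visits) and `mnlv` (mean minutes per
visit). Clusters with `mnlv` below 10 minutes are remanded to transit (brief
pass-throughs). If Step 1 left home undetermined, the cluster with the most
total minutes becomes home and its points define the buffer zone. Work is
the remaining cluster maximising `nsv × mnlv` subject to at least
`work_min_visits` (3) visits of at least `work_min_duration_min` (60)
minutes — an operationalisation of "visited frequently and for extended
periods"; if none qualifies, the participant has no detected workplace
(not everyone commutes). All other clusters are `other` with unique tags.

**Step 4 — gap interpolation and indoor/outdoor.** GPS loss indoors is
heavy (the generator defaults to 40% of indoor minutes, a realistic figure
for an indoor-dominated week). For each run of missing-fix minutes bounded
by valid fixes: if the bounding fixes are within `fill_radius_m` (100 m) of
each other and the run is at most `max_gap_min` (240), the unit plausibly
never moved — the run is filled with the last-known position and inherits
its static label; if the bounding fixes are far apart the run is a transit
candidate; longer runs and leading/trailing runs stay unclassified (no
extrapolation). Static minutes are then split indoor/outdoor: a minute is
outdoor iff the satellite count and the acceleration both reach
participant-specific quantile thresholds (sky view plus a person moving
about outside). Quantiles — satellites 60th percentile of valid-fix counts,
acceleration 70th percentile — make the rule unit-free; runs shorter than
`io_min_run_min` (5) are merged into their neighbours to suppress
single-minute flicker. Level thresholds with run merging were chosen over
explicit change-point detection on the two signals; the change points are
implied by the run boundaries and the merged rule is simpler to reason
about and test.

**Step 5 — sleep.** Within `home_in`, a minute is sleep iff microphone and
acceleration are below low quantiles (30th and 70th percentile
respectively) and, when PM10 is present, its time derivative is small —
resuspension of coarse particles indicates physical activity in the room.
The binary series is smoothed with a centred 10-minute rolling majority
(ties keep the prior value), which removes brief wake blips; smoothing is
idempotent on runs at least as long as the window. Sleep is only claimed
inside the indoor home microenvironment; naps elsewhere are out of scope.

**Step 6 — journeys and transport modes.** Transit minutes are grouped
into journeys: a static interlude shorter than 20 minutes (strictly) is a
stop within the journey, anything longer splits it. Each journey's
per-minute speed series is partitioned by penalized-contrast segmentation:
a dynamic program minimises the within-segment sum of squared deviations
from segment means with a minimum segment length (`lavielle_lmin`, 3 min)
for each candidate segment count K up to `lavielle_kmax` (10), and K is
chosen by the elbow rule — the largest K whose second difference of the
normalized contrast curve exceeds 0.75. Speed is the segmentation signal by
default (configurable); it is the movement channel that changes most
sharply at mode boundaries. Each segment yields 60 candidate predictors:
31 sensor summaries (start/mid hour, duration, accelerometer and microphone
distribution statistics, satellite diagnostics, fix-validity fraction,
position scatter, docked fraction), 3 questionnaire answers (car ownership,
bicycle ownership, public-transport frequency), 19 movement metrics
(speed aggregates, step lengths, total/net distance, straightness, absolute
and relative turning-angle statistics, hull eccentricity and
perimeter-area-ratio aggregates) and 7 GIS projections (fraction of fixes
within 25 m of highway/railway/sidewalk/cycleway/busway lines; bus and
train stops within 50 m of the path).

A random forest classifies segments into the five modes with probabilistic
output (argmax with a fixed class-order tie-break). Predictors are chosen
by a three-step selection: (1) rank by permutation importance averaged over
repeated forests and drop variables that do not beat the best
shuffled-copy probe variable; (2) fit nested forests over ranked prefixes
and keep the smallest prefix within one SD of the minimum out-of-bag (OOB)
error; (3) add the remaining ranked variables stepwise, retaining one only
if the OOB error drops by more than a data-driven threshold — the mean
absolute OOB variation observed when adding noise variables. The threshold
is always computed from the data, never fixed. Evaluation uses 10-fold
cross-validation with folds of near-equal size, each observation validated
exactly once; folds are grouped by trip by default so minutes of one trip
never straddle the train/validation split (ungrouped folds leak
near-duplicate neighbouring minutes and flatter the error).

## The synthetic cohort

No public deployment data exist for this kind of trace, so the package
ships a ground-truthed generator used by every downstream test. It
emulates: one-week traces at 1-minute cadence for an office worker
(nightly sleep 23:30-07:00 docked at home, weekday commutes rotating
through the five modes, a lunchtime break outdoors, evening shop visits,
garden interludes, a weekend park walk); isotropic GPS noise (10 m SD);
Bernoulli per-minute indoor fix dropout (40%) and Poisson satellite counts
(means 5 indoors, 9 outdoors); unitless accelerometer/microphone levels
ordered by context (sleep quietest, cycling most active) with
multiplicative jitter; a PM10 channel that is flat during sleep and lively
awake, with an evening cooking ramp. Mode speeds are drawn per trip from
overlapping but ordered ranges — walk U(0.8, 1.8), cycle U(3, 7),
bus U(5, 12) with a slow crawl minute at each bus stop, car U(6, 15),
train U(10, 30) m/s; these are simulator defaults chosen to produce
separable yet overlapping classes. Transit follows mode-specific polylines
that coincide with the corresponding GIS layer (trains run on the railway),
so network features are informative the way they are for real trips. An
optional `home_share` target adjusts weekday leave-work times until the
indoors-at-home fraction of minutes matches a requested cohort-level share.
Cohorts jitter home locations and questionnaires per participant, and one
participant per cohort sleeps away from home one night, exercising the
Step-1-undetermined → Step-3 fallback.

What the generator does **not** emulate: building-level multipath and urban
canyons (dropout is i.i.d., not spatially structured), second homes and
shift work, diary-style labelling errors (available separately as a delay
perturbation in the evaluation tests), pollutant chemistry, and crowded
GIS networks where several modes share one corridor. Passing tests on this
cohort therefore demonstrate that the implementation recovers the
structure it models — not field performance on real deployments, where
overlapping infrastructure and messier sensor behaviour will lower
headline scores.

## Numerical choices and degenerate inputs

* Timestamps are stored UTC; the night rule applies a per-participant
  minute offset. A fix is valid iff both coordinates are present and at
  least 3 satellites were visible; fix validity is itself a signal.
* Duplicate timestamps collapse by channel averaging (docking by
  majority); malformed rows are dropped and counted.
* Quantile thresholds use the linear-interpolation convention
  (`type = 7`).
* Degenerate hulls (area 0) carry an infinite perimeter-area ratio and are
  flagged; they count for isopleth membership but contribute no area.
* The segmentation dynamic program equals exhaustive enumeration on short
  series (property-tested); constant series short-circuit to one segment.
* k-means and every forest fit are seeded; mode-model training sorts its
  rows canonically first, so training is invariant to input row order.
* Undefined evaluation ratios (zero denominators) are reported `NA`,
  never 0; unclassified minutes score as negatives for every positive
  class.

## Problem sizes used in the shipped checks

The package's own acceptance checks run a 5-participant × 7-day cohort
(50,400 minutes) through all six steps, a 150-trip (30 per mode) grouped
10-fold cross-validation of the mode classifier, 20 seeded repeats of
variable selection on 2 informative + 20 noise predictors, and
100-instance brute-force oracle comparisons for each geometric and
counting primitive. These sizes give stable statistics for every reported
quantity while keeping a full run in the order of a minute on one core.

## Known limitations

* The indoor/outdoor rule assumes the wearer moves when outdoors at a
  static site; a person sitting still in a park reads as indoor.
* Sleep is restricted to the home-indoor microenvironment by design.
* Only the primary workplace is detected; secondary workplaces appear as
  `other`.
* GIS subclassification of `other` locations (shops vs stations vs
  campuses) is out of scope.
* The gap-filling rule cannot recover long indoor absences
  (> `max_gap_min`) and never extrapolates at trace edges.
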