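---
title: "Methods: from seal-borne sensors to seasonal and oceanographic drivers of diving"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from seal-borne sensors to seasonal and oceanographic drivers of diving}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sealdive` implements an analysis chain for harbour-seal biologging data
collected with CTD Satellite Relay Data Loggers (CTD-SRDLs): instruments
that transmit Argos positions, compressed dive records, 6-h dive summaries
and upcast CTD profiles. The chain runs from raw tables to the statistical
models that ask how season, the mixed layer and wind-driven upwelling shape
diving behaviour. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic validation does
and does not establish.

## Track processing

**Speed-distance-angle (SDA) filter.** Argos positions carry class-dependent
errors and occasional gross outliers. The filter removes, iteratively, (i)
locations whose implied swimming speed against both neighbours exceeds
`vmax` (default 2 m s^-1^; the single worst violator by maximum implied
speed is removed per pass, then speeds are re-evaluated), and (ii) "spikes":
vertices whose interior angle is below 15° with both adjacent segments
longer than 2.5 km, or below 25° with both segments longer than 5 km.
Distances are haversine on a spherical Earth (R = 6371 km); the interior
angle is measured from the great-circle bearings at the vertex, with 0°
meaning a full reversal. The first location of a track is never removed, and
the last is tested against its single leg. Removing a point can only merge
two legs into one with a lower implied speed, so the speed pass terminates
and the filter is idempotent (filtering its own output removes nothing);
both properties are tested, along with equivalence against a brute-force
re-check.

**State-space track model.** Filtered tracks are modelled per animal as a
continuous-time correlated random walk: position is the integral of an
Ornstein-Uhlenbeck velocity with reversion rate β (h^-1^) and noise scale σ
(km h^-3/2^), observed through isotropic Gaussian measurement error with a
per-class SD (defaults 0.25/0.5/1.5/4/8/15 km for classes 3/2/1/0/A/B —
configuration values in the usual magnitude regime, not asserted literature
numbers). β and σ are estimated by maximum likelihood via the Kalman filter
on a local tangent plane; smoothing uses the RTS recursion. During haul-out
intervals (dry sensor continuously for more than 10 min) the state
transition holds position and zeroes velocity and process noise, so any
prediction inside a haul-out returns the interval's anchor location exactly.
`locate()` augments the filter/smoother grid with the query timestamps, so
dive and cast positions are conditional means given the whole track.

## Dive metrics

**Bottom time** is the time spent deeper than 80% of a dive's maximum
depth, computed on the broken-stick profile (four transmitted inflection
points completed with surface endpoints) with exact threshold crossings per
linear segment. "Exceeding 80%" is read as strict `>`; crossings at exactly
the threshold have zero measure, so the choice is numerically immaterial but
fixed.

**Effort residuals.** Bottom time is regressed per animal on maximum depth
and duration (OLS); residuals are divided by their own SD so each animal's
vector has mean 0 and SD 1. Positive values mean more bottom time than
expected at that depth/duration. A numerically perfect fit (residual SD
below 1e-8) leaves residuals unscaled rather than amplifying machine noise.

**Dive types.** Dives over bathymetry shallower than 50 m are *coastal*;
otherwise the ratio of dive depth to bathymetric depth classifies *benthic*
(ratio > 0.95) versus *pelagic* (ratio < 0.95). A ratio of exactly 0.95 is
assigned to pelagic (the rules as stated leave the tie open; this choice is
documented and tested). Missing bathymetry yields an unclassified dive with
a logged count.

**Diel bins** are half-open hour intervals in the configured timezone
(default UTC, roughly solar time minus one hour at these longitudes):
night [0, 6), day [6, 18), night [18, 24).

**Time spent in area (TSA).** The smoothed track is sampled at a fixed step
(default 10 min) and elapsed time is allocated to square grid cells (default
5 km) by exact segment-in-cell length fractions; haul-out time is excluded.
Per individual, cells at or above the 75th percentile (linear-interpolation
percentile over cells with positive time) of that individual's cell times
are high-usage; dives located in them are "high-usage dives". Allocated time
sums to elapsed time to well within 0.1%, which is tested. The smoothed
track (not raw locations) is used; a configuration switch could use raw
positions, but the smoothed track is the defensible default because raw
Argos scatter inflates apparent range use.

## Hydrography

**Equation of state.** Potential density anomaly σ~θ~ uses the UNESCO/EOS-80
polynomials (density and adiabatic lapse rate, RK4 integration to surface
pressure), verified in the tests against the published UNESCO check values,
which pin the polynomials down completely. At shelf temperatures, salinities
and pressures the difference from the newer TEOS-10 formulation is of order
10^-3^ kg m^-3^, two orders of magnitude below the MLD threshold. Pressure
is taken as depth in dbar (1 dbar ≈ 1 m here); a latitude-aware conversion
is available behind a flag.

**Mixed-layer depth.** σ~θ~ is computed per cast level; the reference value
is interpolated at 6 m (the first data point of a dive, below wave-driven
surface turbulence). The MLD is the shallowest depth at which σ~θ~ meets the
reference plus `dsigma`, located by linear interpolation between bracketing
levels. `dsigma` defaults to 0.03 kg m^-3^, a common density-threshold
criterion; the threshold is configuration and is reported in output
metadata, since the density-profile method itself does not fix a number.
Casts that never cross the threshold return their deepest level flagged
`bottom_limited`; casts shallower than the reference are invalid. Because a
threshold criterion detects the *top* of the pycnocline, recovery is
assessed against a sharp (sub-metre) interface; with 5-m level spacing the
estimate stays within one level spacing of a sharp interface in ≥ 95% of
casts (measured ≈ 99%).

**3-D temperature/salinity assignment.** Each dive's T and S at the surface
(6 m) and at maximum depth are Gaussian-weighted running averages over all
cast levels of all animals: weight = product of three kernels with SDs 3
days (time), 25 km (great-circle distance) and 5 m (depth, twice the sensor
resolution). The product kernel is the standard axis-separable reading of a
"3-D spatial and time" weighting. Estimates are exact at an isolated cast
point, convex combinations of contributing values, and match a brute-force
double-loop oracle to 1e-9 (tested). Totals below a weight floor (1e-6)
give a flagged no-support result. A time-window truncation (in units of the
time SD) bounds the level scan for speed; the default pipeline uses 4 SDs,
a relative weight error below e^-8^. Casts are shared across animals: a dive
may borrow casts from neighbouring individuals.

**Regions and water masses.** Casts are assigned to three latitude-band
boxes (A north-west, B central, C south; west/south edges inclusive) and
summarised per box, depth level (6/50/100/150 m) and day with a Gaussian
smoother. A "2-day window" is interpreted as SD = 1 day truncated at ±2
days; smoothing preserves a constant series exactly, and days without
support are gaps, never zeros. Water-mass labels follow the descriptive
ranges of the regional water masses — Atlantic Water: T > 3 °C and
S > 34.9; Arctic Water: T < 1 °C and S ≤ 34.7; otherwise mixed — and are
configuration, not a formal oceanographic definition.

## Linking diving to the ocean

**Divergence series and change point.** Daily pooled mean dive depth (shelf
dives, complete days only) is joined to the daily mean of valid, non-
bottom-limited cast MLDs; the series `diff = MLD − mean dive depth` is
analysed raw. A 3-day triangular-weighted smoothed copy is attached for
plotting only — smoothing before testing would inflate autocorrelation. The
change point is the at-most-one-change maximum-likelihood split under a
normal model (exhaustive search; statistic `n log(RSS0/RSS1)`), declared
significant above an MBIC-style penalty `3 log n`. Under pure noise the
false-positive rate at this penalty is below 10%, and a 2-SD mean shift is
localised within ±2 days in ≥ 90% of replicates (both tested by
simulation).

**Wind covariates.** For date *d* and lag *k*, the covariate averages the
wind records in `[d − k, d)` whose direction of origin falls in the sector:
"N" within ±45° of true north, "NE" the north-through-east band. Inputs are
blowing-toward components (u east, v north), so wind *from* the north has
v < 0; a configuration flag accepts the meteorological from-convention.
Records outside the sector do not contribute; an empty window gives 0. Wind
stress (ρ~air~ C~d~ |U|U with ρ~air~ = 1.25 kg m^-3^, C~d~ = 1.3 × 10^-3^)
is available as an alternative unit; mean speed is the default. Windows
crossed by record gaps longer than half the window are flagged.

**Lag selection and the assignment kernel.** The daily bottom-T/S responses
for the lag-grid models are built with a *day-scale* temporal bandwidth
(SD 0.5 d) rather than the 3-day assignment kernel. The reason is
methodological, not cosmetic: a symmetric 3-day smoothing of the response,
combined with backward-looking window covariates, biases the selected lag
upward by about two days (verified against ground truth, where the
unsmoothed response recovers the injected lag exactly). The 3-day kernel
remains the default for per-dive hydrographic assignment, where its purpose
— borrowing strength across sparse casts — is appropriate. With this
choice, the injected wind-to-intrusion lag is recovered exactly as the
best-BIC lag for both 3- and 7-day injections.

## The statistical layer

Seasonal models are penalised-regression-spline additive mixed models
(cubic regression splines, default basis dimension 10 per year-smooth; the
reported depth curve in the full-scale analysis uses k = 20 so the basis
can track the mid-winter transition): one smooth of day-of-season per year,
an animal random intercept, and AR(1) within-animal residuals
(`phi` estimated). Smoothing is selected by REML for reported fits; model
comparison across fixed-effect structures refits by ML. BIC uses n = number
of observations (not groups) — mixed-model BIC conventions differ, so this
accounting is stated in the output. BIC weights are
`exp(−ΔBIC/2)` normalised over the full candidate set before any display
filtering (the display filter keeps rows with weight ≥ 0.01 but retains the
rest). The Poisson daily-count model is fitted as a penalised Poisson
additive model with an animal random-effect smooth and no AR(1) term, since
the chosen backend cannot combine Poisson errors with a residual AR(1); the
fit is flagged accordingly.

Diel models are linear mixed models per month on log-transformed 6-h
responses with animal random intercepts and AR(1); sex terms enter the
candidate set only for September-December, where both sexes still transmit.
Dive-type composition is a multinomial logistic model over
{null, month, month + year, month × year, + age} with BIC selection; sparse
category-month cells are stabilised with a small ridge penalty (decay
1e-4) and flagged. Predicted probabilities sum to one by construction and
are tested to 1e-9.

## The synthetic deployment

The generator emulates the study conditions so that every downstream stage
has a known truth. Its defaults *are* the conditions: ten animals from 1
September to 9 May; autumn (Sep-Nov) transmitted-dive depths with marginal
mean 41 m and SD 24 m; a mixed layer deepening from 38 m to 108 m at
mid-February and shoaling to 70 m; a divergence onset on 27 December after
which dives target 80 m below the mixed layer (the pooled winter peak daily
mean emerges at ≈ 150 m after population normalisation and seabed capping);
a night-time diel effect (depth × 1.15, counts × 1.4) in September-November
only; ~20 Argos fixes per day with 2% gross outliers; ~16 transmitted dives
and 2 casts per animal-day; and Atlantic Water intrusions below a 100-135 m
interface whose warm/saline anomaly scales with the mean northerly wind
over the preceding 7 days (configurable) above 7.2 m s^-1^, reaching
3-4.8 °C and S ≥ 34.9 during events.

Structural choices worth knowing:

* **Stratified heterogeneity.** Per-animal depth multipliers are lognormal
  *quantiles* (SD~log~ 0.45), so the realised between-animal spread — the
  dominant term in the 24-m marginal SD, as in the per-individual spread of
  real deployments — is stable across seeds, while each animal's noise
  streams derive from (seed, animal index) and are independent.
* **Terraced shelf.** Bathymetry is flat benches (35/75/120/185 m) joined
  by 2-km ramps. Dive-type truth depends on bathymetry at the *true*
  position while the pipeline looks it up at the *located* position;
  terraces make that lookup insensitive to the ~1 km residual location
  error except in the narrow ramps, which is exactly the situation on a
  low-gradient shelf. The ≥ 99% class-agreement result should be read with
  that in mind: on steep slopes agreement would be limited by location
  error, not by the classifier.
* **Wind-lagged intrusions.** The deep anomaly at day *d* is a continuous
  function of the windowed northerly wind, so the injected lag is a
  well-defined generative quantity rather than an event bookkeeping
  convention; "events" in the ground truth are the runs of days where the
  windowed wind exceeds the threshold.

What the generator does **not** emulate: hydrodynamics (no Ekman physics,
no advection; the intrusion is imposed, not simulated), ice drift and
ice-behaviour coupling (the ice grid is a static gradient used only as a
candidate covariate), sensor drift or salinity spikes, Argos error
anisotropy, and prey fields. Passing the recovery checks therefore shows
the *estimators* are correct and well-calibrated under the assumed
statistical structure — not that the structure is true of any real ocean.

## Problem sizes and determinism

The full-scale validation uses the default conditions: ~40,000 transmitted
dives, ~50,000 Argos fixes, ~5,000 casts (~80,000 levels) over 250 days;
the generator plus the complete pipeline runs in about 1.5 min on one CPU,
and the change-point calibration uses 200 series-level replicates. Unit
tests run on much smaller constructed cases. All randomness descends from
one integer seed; identical seeds give identical outputs byte for byte,
which is tested, and per-animal streams make partial re-simulation stable.

## Known limitations

* The CTCRW measurement SDs are fixed per class, not estimated; grossly
  misstated SDs would propagate to location SEs (though weakly to point
  estimates).
* `gamm`-based fits can be fragile on degenerate inputs (zero variance,
  single animal); the Poisson count model drops the AR(1) term by design.
* The change-point model assumes a single mean shift with independent
  normal errors; the divergence series is autocorrelated day-to-day, so the
  MBIC penalty is conservative in calibration terms rather than exact.
* Lag selection among backward windows is only identified up to the
  temporal resolution of the response series; see the bandwidth discussion
  above.
* Region boxes are fixed latitude bands; real frontal geometry is not
  box-shaped.
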