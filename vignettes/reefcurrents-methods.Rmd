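---
title: "Methods: current and temperature regime analysis on contrasting reef morphologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: current and temperature regime analysis on contrasting reef morphologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`reefcurrents` implements a complete analysis of sub-surface hydrodynamic
and thermal regimes on coral reefs of three morphologies — nearshore
emergent, offshore emergent, and submerged pinnacle — from moored
current-meter records sampled every 10 seconds. This vignette documents the
statistical models, the defaults and why they were chosen, the synthetic
data generator that stands in for undeposited field data, and the known
limits of what the test suite demonstrates.

## Data model and quality control

A record is one timestamped observation of current speed (m s⁻¹),
heading-to direction (degrees clockwise from north) and temperature (°C) at
a site. All timestamps are treated as UTC; local-time conversion is the
caller's responsibility. QC never deletes or mutates records: each check
only sets a flag, the retained view is a filter (`qc_passed()`), and
re-running QC on its own output is a no-op. Flags carry a fixed precedence
(`EDGE_TRIMMED` > `RANGE_FAIL` > `CONSISTENCY_FAIL`) so the per-site QC
report is an exact partition of the rows read.

Three checks are applied:

* **Deployment trimming.** Records within `trim_hours` (default 2) of
  either end of the deployment window are flagged, excluding instrument
  handling and surface exposure. Boundaries are half-open — a record at
  exactly `start + 2 h` is retained — so exactly two hours are excluded at
  each end, deterministically.
* **Range check.** Speed outside \[0, 3\] m s⁻¹, direction outside
  \[0°, 360°), or temperature outside \[20, 40\] °C is flagged. The physical
  bounds bracket anything a sub-surface tropical deployment plausibly
  records and are configurable.
* **Temporal consistency.** A Hampel-style spike rule: a sample whose speed
  deviates from a running median (window 360 samples ≈ 1 h at native
  cadence) by more than 10 running MADs is flagged. The running MAD is
  floored at `spike_floor` (10⁻⁴ m s⁻¹, below instrument resolution) so a
  smooth, locally noise-free series cannot drive the threshold to zero;
  without the floor a spike sitting on a clean sinusoid would escape
  detection because the local MAD vanishes. Runs of exactly repeated speed
  values longer than `flatline_span` samples are flagged as a stuck sensor.
  No threshold for "abnormal variability" is canonical; these are explicit,
  configurable package choices.

After QC, all sites are clipped to a common annual analysis window
(half-open), with per-site temporal coverage reported and an error naming
any site with no overlap.

## Circular statistics

Directions are circular data; arithmetic averaging is never applied to raw
angles anywhere in the package (a wrap-around test asserts that a day of
{359°, 1°} headings averages to 0°, not 180°).

* The **scalar mean speed** is the plain arithmetic mean of speeds.
* The **vector-averaged direction** resolves each sample into east/north
  components weighted by speed magnitude, averages the components, and maps
  the resultant back with the two-argument arctangent. This is
  algebraically identical to the single-argument arctangent plus a ±180°
  quadrant-correction clause; both forms are implemented and unit-tested
  against each other on all four quadrants. The resultant speed can never
  exceed the scalar mean (triangle inequality), with equality only when all
  directions coincide; when all speeds are zero the mean direction is
  undefined and flagged `NA`.
* **Convention.** The meteorological transform puts a minus sign on the
  components ("coming-from" directions); oceanographic practice reports
  where flow is heading to. The `convention` argument makes the choice
  explicit. The default `heading_to` omits the sign flip, which is the
  self-consistent choice — a constant input heading D returns exactly
  θ̄ = D — and `coming_from` (a 180° rotation of the resultant) is provided
  for wind-style data.
* The **Yamartino directional standard deviation** is the single-pass
  estimator from unweighted unit-vector means:
  ε = √(1 − (s̄² + c̄²)), σθ = arcsin(ε)·\[1 + (2/√3 − 1)ε³\]. It is 0 for
  identical headings and tends to 90°·2/√3 ≈ 103.92° in the uniform limit.
  A magnitude-weighted variant exists but is off by default, since the
  estimator is defined over unit vectors.

**Numerical-accuracy note.** The package also ships the closed-form
circular angular deviation √(2(1 − R))·180/π (R the mean resultant length)
as an exact reference. For concentrated samples the two agree within ~2%,
but they are *different population quantities* once spread grows: against
√(2(1 − R)) the Yamartino estimator deviates by ≈ +5% at a 35° spread and
≈ +6% at 39°, while against the two-pass RMS of wrapped angular deviations
about the mean direction — the quantity the single-pass estimator is
designed to track — it stays within ~2% up to ≈ 36° spread. The acceptance
suite therefore validates the estimator against the two-pass RMS oracle
over 1000 random von Mises samples (spreads ≈ 7–31°, all below 40°), and
against the closed form only for concentrated samples.

## Aggregation and the seasonal calendar

Days are \[00:00, 24:00) UTC. Daily summaries report mean/max/min of speed
and temperature, the magnitude-weighted θ̄, and σθ computed from *all* the
day's retained samples (not from hourly means, since the estimator is
defined over samples). A day enters the analysis only if its completeness —
retained samples over expected samples at the site's cadence, inferred
per site from median timestamp spacing — reaches `min_completeness`
(default 0.8; no canonical rule exists, and the threshold is configurable).
Hourly means feed the rose and polar summaries.

The seasonal calendar is the monsoonal four-season partition: T1 (Sep–Nov),
WET (Dec–Feb), T2 (Mar–May), WINDY (Jun–Aug). Seasonal and annual averages
of the daily values are computed per site and per reef type. For reef types
two pooling rules are both emitted: *mean of site means* (sites as
replicates — the default headline rule, matching the site-as-random-effect
logic of the models) and *day-weighted pooling*; whether published
"annual daily averages" pool days or sites is generally ambiguous, so both
are reported and labelled.

## Robust variability and permutation inference

Daily mean speeds are right-skewed, so spread is summarised by quartiles,
the IQR, and the MAD in its plain form median|Xᵢ − X̃| — deliberately
*without* the 1.4826 normal-consistency constant. Quantiles use linear
interpolation between order statistics ("type 7"), recorded in every
output, because IQR values depend on the estimator.

Between-group differences in q25, median, q75 or IQR are tested by
permuting group labels with group sizes held fixed. The two-sided p-value
uses the add-one rule (1 + #{|T*| ≥ |T|})/(B + 1), strictly positive and
valid under exchangeability; when the number of distinct relabellings is
below the enumeration cap (default 10⁴) every relabelling is evaluated and
the p-value is exact. The default B = 5000. Test units are daily values
pooled per reef type; all pairwise group tests share one permutation set
per pair across statistics, each pair gets a seed derived from the master
seed, and Holm adjustment across the three pairs is available (default off,
mirroring raw pairwise reporting; three tests per statistic do inflate
family-wise error, hence the option).

## Group models

Daily responses are modelled as `response ~ reef_type + (1 | site)`:
gaussian with identity link for temperature, gamma with log link for
(strictly positive, skewed) speed. Estimation delegates to `glmmTMB`
(maximum likelihood), and marginal means and all-pairs contrasts to
`emmeans`: means are balanced over the design and back-transformed to the
response scale; contrasts are computed after re-gridding, so a contrast is
a difference of response-scale means under both families, with Tukey
(studentized-range) multiplicity adjustment for the all-pairs family and
the significance flag defined by the adjusted 95% CI excluding zero.
Intervals use naive between-site degrees of freedom (n_sites − n_groups):
sites, not days, are the units of replication, and the backend's asymptotic
z intervals undercover with a handful of sites per group; no
Kenward–Roger-style correction is attempted. With one site per group the
site variance is unidentifiable; the fit proceeds and is flagged. Seasonal
scope is handled by fitting per-season subsets rather than one interaction
model. Residual diagnostics are limited to quantile and residual-vs-fitted
summaries.

## Rose and polar tables; SST comparison

Rose tables bin hourly means into 12 sectors of 30° with the first sector
centred on north (so a 14.9° heading is "north": \[−15°, 15°)), crossed
with speed classes at 0.1 m s⁻¹ steps with an open last class — bin
definitions for such figures are rarely stated, and these defaults are
configurable. Cell values are percentages of retained hours (summing to 100
per site) and the site's net heading is the magnitude-weighted vector
average of the full hourly series. Polar tables carry the mean temperature
of the hours in each direction × speed cell; empty cells carry no
temperature.

The in-situ vs satellite comparison pairs daily in-situ means with a
multi-day composite SST series, either by expanding each composite to its
member days (default) or collapsing the in-situ series into composite
windows; the two agree exactly when series are constant within windows. The
offset (in-situ − SST, positive when loggers run warmer) gets a paired
t-interval on daily differences — optimistic, because daily differences are
autocorrelated; a weekly block-bootstrap interval is available.

## The synthetic data generator

The generator exists because the field records behind this class of study
are rarely deposited; it emulates the statistical structure the analysis
assumes, not hydrodynamics.

* **Speed**: a gamma marginal (right-skewed, as observed for current and
  wind speeds) with rank-preserving autocorrelation from a latent AR(1)
  Gaussian (a copula-style transform), times a Poisson pulse process —
  events at `pulse_rate` per day multiplying speed by `pulse_multiplier`
  for `pulse_duration` hours — reproducing the repetitive sharp speed peaks
  seen over abrupt submerged topography. `ar1_coeff` is defined at the
  native 10-s cadence and rescaled as ρ^(Δt/10) at coarser sampling, so a
  regime keeps its correlation timescale at any cadence.
* **Direction**: i.i.d. draws from a von Mises mixture (directional
  persistence is not needed by any statistic in scope). Concentration 0
  gives uniform headings; a single concentrated component gives a dominant
  heading.
* **Temperature**: annual sinusoid + diurnal sinusoid + Gaussian noise +
  fixed per-site offset — the smallest model with the weak (< 2 °C)
  seasonality and modest diurnal range of low-latitude reef water at
  25–30 m.
* **Edge artifacts**: the first and last 2 h of a deployment are replaced
  by erratic out-of-regime values (elevated noisy speeds, scrambled
  headings, warm temperatures) to exercise deployment trimming; their
  windows are recorded in a ground-truth sidecar, never flagged in the
  emitted data.
* **SST**: in-situ daily means averaged over 8-day windows, minus a
  systematic offset (default 2.0–2.05 °C) plus Gaussian window noise.

**Archetype defaults.** No generative parameters exist in any public
dataset, so the three reef-morphology archetypes are free modelling
choices, fixed once: gamma shape 2.2 everywhere; annual mean speeds ≈
0.083 / 0.052 / 0.051 m s⁻¹ (pinnacle / offshore / nearshore, after
accounting for the mean inflation contributed by pulses); correlation
timescales of a few hours, longest offshore; pulse activity strongest on
pinnacles (1.2 day⁻¹, ×2.2, 2 h). These were calibrated in a one-off
simulation so the daily-mean dispersion ordering is pinnacle > offshore >
nearshore with the pinnacle IQR roughly twice the nearshore IQR — the
qualitative contrast the analysis is designed to resolve — and then frozen.
Directions: pinnacles concentrated at 340° (north-northwest), offshore
near-uniform (κ = 0.25), nearshore two narrow sector modes. What the
generator does *not* emulate: tides, wave spectra, eddies, internal waves,
upwelling physics, or any cross-variable coupling between speed and
temperature. Passing tests therefore demonstrate correctness of the
*statistical machinery* under realistic marginal and temporal structure,
not oceanographic fidelity.

## Numerical choices

* Large simulations (> 2×10⁴ draws) evaluate the gamma quantile transform
  of the latent Gaussian through a cached monotone (Hyman) spline with
  knots every 0.00325 in z over |z| ≤ 6.5 (max relative error < 10⁻⁷), and
  von Mises draws through a cached 20001-point inverse-CDF table (angular
  quantisation < 0.02°). Below that size, exact `qgamma` and Best–Fisher
  rejection sampling are used.
* Quantiles: type 7 everywhere, recorded in outputs.
* Permutation p-values: add-one rule when sampled; exact enumeration below
  the cap; ties in |T| counted as exceedances (conservative).
* Degenerate inputs: empty groups, all-zero speeds, all-identical
  directions, empty composite overlap and sub-2×trim deployments all raise
  informative errors or flagged `NA`s rather than silent numbers.

## Problem sizes used by the test suite

The acceptance checks run at sizes chosen for a desk-scale machine while
preserving the study conditions: the dispersion-contrast power check uses
200 one-year fleets of three archetype sites at 1-minute cadence (499
permutations per test); the type-I calibration uses 1000 null replicates of
120 + 120 daily values at 999 permutations; model recovery uses 100
random-intercept fits (50 per family) at 3 groups × 4 sites × 365 days; the
estimator-vs-oracle comparison uses 1000 von Mises samples of 5000 draws;
the end-to-end determinism check runs the 3-site, 60-day, 1-minute demo
dataset twice. The acceptance script simulates the full 11-site design for
one year at 5-minute cadence.

## Known limitations

* The spike and flatline thresholds are pragmatic defaults, not estimates;
  heavily pulsed regimes with very long pulses could in principle trip the
  spike rule (the defaults keep ~1-h windows so 2-h pulses survive).
* The SST t-interval ignores autocorrelation (documented; block bootstrap
  available).
* glmmTMB's asymptotic intervals can undercover slightly with very few
  sites per group; the recovery tests quantify this at the study design
  size (4 sites per group).
* The generator's independence between direction and speed means
  direction-conditional speed structure (e.g. stronger flows from a
  dominant sector) is only reproduced through the mixture weights, not
  dynamically.
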