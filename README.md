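# reefcurrents

Sub-surface current and temperature regimes on contrasting coral-reef
morphologies, from moored current-meter records.

## The problem

Submerged coral pinnacles — small, steep-sided reefs whose crests lie well
below the surface — are physically analogous to seamounts, and interactions
between impinging flows and their abrupt topography are expected to produce
stronger, more variable currents than on emergent reefs at the same depth.
Testing that idea from field data means analysing year-long, high-frequency
(10-s) records of current speed, heading and temperature from drag-tilt
current meters moored at many reef sites, comparing reef morphologies
(nearshore emergent, offshore emergent, submerged pinnacle) across a
tropical four-season calendar, and contrasting in-situ sub-surface
temperatures with satellite sea-surface temperature (SST) composites.

`reefcurrents` packages that entire analysis as composable, tested,
tibble-in/tibble-out functions, plus a synthetic current-meter data
generator with per-morphology archetypes so the full pipeline runs and is
testable without any field download.

## The statistics at its core

* **Scalar mean speed** \(\bar{u} = n^{-1}\sum_i u_i\), and
  **magnitude-weighted vector averaging** of heading:
  \(\bar{u}_x = \overline{u_i \sin\theta_i}\),
  \(\bar{u}_y = \overline{u_i \cos\theta_i}\),
  \(\bar\theta = \mathrm{atan2}(\bar{u}_x, \bar{u}_y)\) mapped to
  \([0^\circ, 360^\circ)\).
* **Yamartino directional standard deviation** from unweighted unit-vector
  means: with \(\varepsilon = \sqrt{1 - (\bar{s}^2 + \bar{c}^2)}\),
  \(\sigma_\theta = \arcsin(\varepsilon)\,[1 + (2/\sqrt{3} - 1)\varepsilon^3]\),
  bounded by \(90^\circ \cdot 2/\sqrt{3} \approx 103.92^\circ\).
* **Robust dispersion** of daily mean speeds: quartiles, IQR, and the MAD in
  its plain form \(\mathrm{median}|X_i - \tilde{X}|\) (no consistency
  constant), compared between reef types with **label-permutation tests**
  on percentile statistics (add-one two-sided p; full enumeration when
  feasible).
* **Random-intercept group models**: daily responses modelled as
  `response ~ reef_type + (1 | site)`, gaussian/identity for temperature and
  gamma/log for speed, with response-scale estimated marginal means and
  Tukey-adjusted pairwise contrasts (significant when the adjusted 95% CI
  excludes zero).
* **Rose / polar summary tables** from hourly means, and the **in-situ
  minus SST offset** with a paired t-interval.

## A worked example

```r
library(reefcurrents)

dir <- tempfile()
demo_dataset(dir, seed = 42)           # 3 archetype sites, 60 days, 1-min cadence
cfg <- demo_config(dir)
manifest <- run_full_analysis(cfg)     # writes CSVs + manifest under dir/output

readr::read_csv(file.path(dir, "output", "dispersion_summaries.csv"))
#> # A tibble: 3 x 8
#>   group                  n    q25 median    q75    iqr     mad percentile_method
#>   <chr>              <int>  <dbl>  <dbl>  <dbl>  <dbl>   <dbl> <chr>
#> 1 nearshore_emergent    60 0.0414 0.0485 0.0611 0.0197 0.00782 type7
#> 2 offshore_emergent     60 0.0384 0.0569 0.0822 0.0438 0.0223  type7
#> 3 pinnacle              60 0.0559 0.0864 0.105  0.0490 0.0233  type7

readr::read_csv(file.path(dir, "output", "sst_offset.csv"))[1, 1:4]
#> # A tibble: 1 x 4
#>   estimate lower upper     n
#>      <dbl> <dbl> <dbl> <dbl>
#> 1     2.13  2.08  2.19    60
```

The dispersion table shows the regime contrast the package is built to
resolve: the pinnacle site's daily-mean speeds (median 0.086 m s⁻¹) run
well above the emergent sites' (≈ 0.05 m s⁻¹) and its IQR (0.049 m s⁻¹) is
about 2.5× the nearshore site's (0.020 m s⁻¹); with a single 60-day site
per type the offshore draw happens to be nearly as variable as the
pinnacle — at the full 11-site annual design the ordering pinnacle >
offshore > nearshore resolves cleanly (see the acceptance script below).
The SST comparison recovers the simulated ~2 °C in-situ-minus-satellite
offset.
`permutation_tests.csv`, `model_speed_mean_means.csv` and
`rose_table.csv` in the same directory carry the inferential results and
figure backbones.

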