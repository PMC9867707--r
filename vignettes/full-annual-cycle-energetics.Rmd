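---
title: "Full annual cycle energetics from GPS and accelerometer biologging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full annual cycle energetics from GPS and accelerometer biologging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fullcycle)
```

## The problem

Migratory seabirds such as lesser black-backed gulls (*Larus fuscus*) breeding
in the Netherlands winter anywhere between the UK (a few hundred km away) and
West Africa (beyond 4500 km). Whether migrating further costs more energy over
a whole year, or merely redistributes expenditure in time, can only be judged
with a *full annual cycle* budget: daily energy expenditure (DEE) and
time-activity budgets reconstructed from June 1 of one year to May 31 of the
next. `fullcycle` implements that reconstruction from year-round GPS fixes
paired with 1-s tri-axial acceleration bursts, plus per-fix weather, and adds
a synthetic-data generator so every stage of the pipeline is testable without
field data.

## The model

**Dynamic body acceleration.** Each fix carries a 1-s burst at 20 Hz. The
static (gravitational) baseline is removed by subtracting the per-axis mean
over the recording chunk; DBA is then the per-sample vector norm
$\sqrt{x^2+y^2+z^2}$ of the remaining dynamic acceleration, averaged over the
burst. Averaging (the VeDBA convention) rather than summing makes the value
independent of burst length; the usual shorthand formula is ambiguous between
the two readings, and the averaged form matches the calibration literature
the cost coefficients come from.

**Activity costs.** Behavior labels from an upstream classifier are reduced to
four modes. Non-floating stationary fixes use a respirometry calibration,
$\mathrm{MR}\,(\mathrm{W}) = 4.80 + 49.80\,\mathrm{DBA}$ (DBA in g); flapping
flight, soaring flight, walking and floating use fixed average costs of 32,
7.9, 8.5 and 6.6 W, ignoring DBA — behavior-specific DBA calibrations could
not be derived for these modes, so average costs stand in.

**Thermoregulation.** Resting birds must also pay to keep warm. The
heat-exchange model uses the operative temperature
$T_e = T_a + g_r R_g$ (air temperature plus a radiative increment from solar
radiation, default $g_r = 0.01\,^\circ$C per W m$^{-2}$) and a wind-scaled
thermal conductance $K(u) = k_0 (1 + c_w \sqrt{u})$ (defaults
$k_0 = 0.25$ W $^\circ$C$^{-1}$, $c_w = 0.2$). At or above the lower critical
temperature ($T_{lc} = 10\,^\circ$C for this species) the cost is the basal
rate (default 4.59 W, i.e. 396.4 kJ day$^{-1}$); below it,
$\mathrm{MR} = \mathrm{basal} + K(u)(T_{lc} - T_e)$. Species-calibrated
coefficients for shorebird/waterfowl heat-exchange models exist in the
respirometry literature but are not transcribed here; the defaults preserve
the model's monotone structure (colder, windier, darker is costlier) at
physiologically plausible magnitudes for an ~800 g gull, and every constant
is a `thermo_config()`
field loadable from configuration. Floating costs carry no water-conductance
surcharge and heat stress at high temperatures is not modeled — two
deliberate simplifications of the bioenergetics.

**The max-rule and daily aggregation.** Thermoregulatory costs are assumed
compensated by activity, so each fix uses
$\max(\mathrm{MR}_{activity}, \mathrm{MR}_{thermo})$. DEE is the day's mean
per-fix MR in W times 86.4 kJ day$^{-1}$ W$^{-1}$. Time budgets allocate 24 h
proportionally to fix counts per mode; flight and stationary metabolic rates
are per-day means over the respective fixes. Annual energy expenditure (AEE)
is the mean of DEE over the bird-year, and is also expressed as a multiple of
a captive resting metabolic rate. The default reference RMR of
396.4 kJ day$^{-1}$ is back-derived from five published (DEE, multiple) pairs,
which agree on it within 1%; it is documented as derived and overridable.

**Segmentation.** Net daily displacement is the great-circle distance
(haversine, sphere radius 6371.0088 km) between the fixes closest to
consecutive UTC midnights (a fix must sit within ±6 h of the midnight, else
the day is missing). Days moving strictly more than 70 km are relocation
days. The annual cycle partitions into breeding, autumn migration, wintering
and spring migration: the last detection within 10 km of the colony ends
breeding, the first detection the following spring restarts it, and the
winter spans the first to last stationary day inside the wintering area. The
wintering area is the southernmost connected component of the 95% level set
of a 2-D Gaussian KDE of nonbreeding positions, fitted on a Lambert azimuthal
equal-area projection. Relocation days within migratory periods are migration
days; stationary days there are stopover days.

**Gap filling.** Solar-powered loggers lose data in dark northern winters.
Discarding gappy bird-years would bias thermoregulatory estimates toward
fair-weather records, so gaps that fall entirely inside a stationary period
are filled by resampling: each missing slot draws a donor fix uniformly from
the same stationary period within ±1 h time of day (widening stepwise to ±3 h
with a warning when donors are missing), keeping the donor's behavior, DBA
and location but the slot's timestamp so thermoregulation uses the weather of
the missing moment. Donors are drawn without replacement while possible. Any
bird-year that relocated across a gap is discarded, and filled fixes count
toward energy but never toward activity-time analyses. Coverage is assessed
before filling; bird-years below 75% of days are excluded.

**Summaries.** Besides AEE, the package computes the sum of deviance
$\sum_t |\overline{\mathrm{DEE}}_w(t) - \mathrm{AEE}|$ for windows $w \in
\{1, 7, 30\}$ days (how concentrated expenditure is in time), the three
highest and lowest non-overlapping 7-day windows per bird-year (greedy, most
extreme first, ties to the earliest date, each labeled with the stage of its
central day), a migration-day table (period lengths, migration-day counts,
mean/max DEE and flight hours, aggregated mean ± SD per strategy and season),
and tidy per-bird-year / per-bird-day tables for external mixed-model
fitting. The package deliberately fits no LMM/GAMM itself.

## The synthetic generator

`strategy_template()` encodes four migration strategies with colony
(52.46° N, 4.58° E), winter centroids at 48.5° N (France/UK), 40° N (Iberia),
31.5° N (North Africa) and 14.7° N (West Africa), per-season migration-day
counts (5/5, 7/9, 9/10, 18/14), migratory-period lengths (33/16, 106/23,
96/19, 123/21 days) and mean daily flight hours on migration days, all at the
published per-strategy scales. Migration days hold one 6–17 h flight bout
(61% flapping / 39% soaring); other days draw each fix's behavior from the
active stage's budget. Stage budgets are calibrated to the published annual
means (≈2.2 h flapping and 1.4 h soaring per day, winter stationary time near
20 h day$^{-1}$, extra walking for the France/UK strategy). Weather is a
closed-form seasonal + diurnal sinusoid with noise, a solar-elevation model
(exactly zero at night) and Weibull winds — enough to give the
thermoregulation model its monotone latitude/season structure; 15° N winters
stay above 10 °C while 52° N winters drop below.

Two deliberate realism choices matter for interpretation:

* **Heterogeneity.** Mean-one lognormal multipliers on the flight and walk
  fractions act at the bird-year level (σ = 0.15) and the day level
  (σ = 0.30), with the displaced fraction absorbed into stationary time. This
  mimics the field observation that day-to-day foraging decisions dominate
  variance, and it keeps expected budgets exactly equal to the template, so
  parameter-recovery tests remain unbiased. Realized per-day budgets are
  stored in the generator's ground truth.
* **Staging hops.** Birds leave the colony with a ~16 km evening hop on their
  last breeding day (and mirror this on arrival), so the colony-radius
  segmentation convention recovers the scheduled boundary dates exactly
  rather than ±1 day.

What the generator does **not** emulate: wind drift and thermal soaring,
tides, habitat rasters, molt costs, body-mass dynamics, heat stress, or
classifier error in behavior labels. Passing tests therefore demonstrate that
the pipeline's definitions and statistics are implemented correctly and
recover known structure; they do not validate the bioenergetic model against
field metabolism.

## Numerical choices

* **KDE bandwidth.** Scott's rule, bounded to [10, 50] km. Unbounded Scott
  over-smooths strongly multimodal nonbreeding distributions (its scale spans
  the whole migration corridor, welding stopover, corridor and winter into
  one 95% component); conversely, for highly site-faithful birds the robust
  data scale collapses to daily jitter and fragments the winter area. The
  bounds keep core areas at the few-hundred-km scale typical of gull
  wintering ranges and are overridable (`bw`, `bw_cap`, `bw_floor`). Grid:
  200 × 200; the level is the largest density whose superlevel set holds ≥95%
  of mass (enclosed mass lands within ~0.02 of 0.95 on these grids).
* **Boundary readings.** "Exceeding 70 km" is strict (a 70.0 km day is
  stationary). Day boundaries are UTC midnights. Missing-displacement days
  flanked by stationary days inherit stationary status; otherwise they stay
  missing.
* **Moving means** use truncated windows at the series edges; deviance sums
  for windows > 1 use full windows only, to avoid edge inflation. Both are
  arguments.
* **Ties.** Equal activity/thermoregulation estimates return the common
  value; equal extreme-week means pick the earliest center date.
* **Statistical criteria at scale.** "Within 3 SE" recovery checks are
  evaluated over on the order of 10³ comparison cells; a correct
  implementation leaves a binomial share (~0.3%) of cells beyond 3 SE, so the
  suite asserts ≥99% of cells within 3 SE and none beyond 5 SE.
* **Problem sizes.** The reference cohort is 20 bird-years per strategy at a
  60-min interval (the study's coarsest); interval-sensitivity checks use
  eight bird-years at 2.5 min (the study's finest) against 20- and 60-min
  thinnings, pooling ~2900 day pairs. These sizes give the cohort statistics
  stable margins while keeping a full run in minutes.

## Worked sketch

```{r, eval = FALSE}
tpl <- strategy_template("WestAfrica")
by  <- generate_bird_year(tpl, sampling_interval = 20, seed = 1)
res <- process_bird_year(by, weather_fun = synth_weather_at)
res$annual$aee          # annual energy expenditure, kJ/day
res$dev                 # sum of deviance, windows 1/7/30
res$extreme             # three highest and lowest weeks with stages
migration_table(list(res))
```

## Known limitations

Thermoregulation constants are structural defaults, not species-calibrated
heat-exchange coefficients; absolute stationary costs in cold weather should
be treated as indicative until calibrated. The KDE
winter-area step assumes the wintering cluster is the southernmost core area,
which fails for hypothetical birds wintering north of a stopover. Weather
enters per fix; no raster extraction is provided. Habitat analysis is limited
to the six-class reduction. The generator's budgets are stage-constant apart
from the lognormal heterogeneity, so it cannot emulate smooth within-stage
phenological trends.
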