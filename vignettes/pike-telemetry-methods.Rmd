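---
title: "Methods: from raw acoustic positions to behavioural repeatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw acoustic positions to behavioural repeatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piketel)
```

`piketel` implements a whole-lake analysis of northern pike (*Esox lucius*)
behaviour under contrasting habitat structural complexity: a
position-processing pipeline for high-resolution acoustic telemetry, daily
behavioural traits, a macrophyte structural-complexity index, trophic and
growth estimators, and repeatability statistics. Because raw field data of
this kind are rarely deposited, the package ships a seeded synthetic-lake
and trajectory generator with the same data structure, so every stage is
testable end to end. This vignette explains the models, the parameters that
matter, and the design choices made where the methods literature leaves the
design open.

## The positioning pipeline

Acoustic transmitters emit a coded burst every 25 s. A burst detected by a
single receiver yields a depth reading (the tag carries a pressure sensor,
reported up to a 35-m sensor ceiling); a burst detected by three or more
receivers can be multilaterated into a planar position. The pipeline starts
from the position-estimate table such a system produces: `tag_id`,
`timestamp`, optional `x`/`y` (m), `depth` (m).

**Filtering** (`filter_positions()`). Multilateration produces duplicates
and occasional large position errors. Three configurable rules are applied:
exact duplicates collapse to one row; fixes outside the shoreline polygon
buffered outward by 50 m are dropped; and fixes implying a sustained speed
above 2 m/s to *both* temporal neighbours are removed iteratively until
stable. Only interior fixes (those with two neighbours) are removable by
the speed rule — an endpoint has a single neighbour, so a displaced endpoint
cannot be distinguished from genuine fast movement and is retained. The
defaults are standard telemetry practice for a fish of this size; all
thresholds are arguments.

**Regularization** (`regularize()`). To remove bias from spatiotemporally
varying detection rates, fixes are averaged over clock-aligned 15-min
intervals (left-closed, right-open on the UTC grid), giving at most 96
"q-positions" per day. Depth is averaged over *all* detections in the
interval, so a q-position can carry depth without coordinates.

**Gap interpolation** (`interpolate_gaps()`). A run of missing intervals is
filled by linear interpolation between the bounding q-positions P and Q only
when all three hold strictly: the P–Q time difference is under 2 h, their
planar distance under 100 m, and their depth difference under 2 m — i.e.
when the fish demonstrably stayed put, so linearity is safe. Interpolated
records are flagged and carry `n_fixes = 0`. Two open details were decided
as follows: interpolation is evaluated at interval midpoints (with a regular
grid the interpolation fractions are identical to boundary-time evaluation),
and distance is planar Euclidean (at lake scale the distinction from
geodesic distance is vacuous).

**Distance to bottom and mortality.** `distance_to_bottom()` subtracts
sensor depth from the bathymetric bottom depth, averaging per-fix distances
within an interval when raw fixes are available (this matters over sloping
bottoms). `flag_mortality()` flags a tag when horizontal position and depth
stay essentially constant from some time to the end of the series (suffix
standard deviations below 5 m and 0.3 m over at least 48 h); the original
criterion was visual, so these thresholds are explicit, configurable
equivalents. A fish that is stationary for a day and then moves again is
not flagged.

## Daily behavioural traits

All traits are computed per individual and calendar day, on raw scales;
variance decomposition applies the log/sqrt transforms later.

* **dH-KUD** (`daily_hkud()`): the 95% kernel utilization distribution of
  the day's coordinates — a bivariate Gaussian kernel with bandwidth
  *h* = 50 m evaluated on the 10 × 10 m lake raster, truncated at the
  shoreline, renormalized to unit in-lake mass, and summarized as the area
  (ha) of the smallest set of highest-density cells holding ≥ 95% of the
  mass. Truncate-and-renormalize was chosen over boundary-kernel correction
  as the simpler, conservative and easily testable treatment. The day
  qualifies only with more than 12 daytime *and* more than 12 night-time
  q-positions ("more than 12" is strict). A degenerate day with all
  positions identical returns the single-cell area (0.01 ha) by contract.
  For speed the Gaussian kernel's separability is exploited (the grid
  density is an outer product of per-axis kernel factors) and evaluation is
  restricted to cells within five bandwidths of the data, where the
  neglected kernel mass is below 10^-6; tests verify agreement with a
  dense-grid direct-summation oracle to 1%.
* **dV-KS** (`daily_vks()`): the same highest-density construction in one
  dimension on the day's depths, with a fixed Gaussian bandwidth of 0.4
  (metres — the natural unit for depth, though the source description does
  not state one) on a 0.05-m grid. With a single distinct depth this
  approaches the closed form 2 × 1.96 × 0.4 ≈ 1.57 m.
* **Activity** (`daily_activity()`): horizontal speed in body lengths per
  second and vertical speed in m/s between q-positions in *adjacent*
  intervals only (900 s apart), averaged over the day. Restricting to
  adjacent pairs avoids downward speed bias across long gaps; interpolated
  q-positions participate, as they represent the regularized series.
* **TOW** (`daily_tow()`): the fraction of q-positions at least 5 m above
  the bottom (exactly 5 m counts as open water), with indicators for
  all-benthic and all-pelagic days.
* Covariates: `daily_temperature()` averages logger readings at 0–3 m per
  date; `day_length()` is dusk minus dawn from the civil-twilight table;
  the diel split (`split_diel()`) calls daytime the window from one hour
  after civil dawn to one hour before civil dusk.

## Habitat structure and prey sampling

The Structural Complexity Index (`sci()`) multiplies discretized macrophyte
height (100 bins of 2 cm; ≥ 2 m saturates) by discretized coverage (100
bins of 1%), ranging 0–10,000. Bins are indices, so the maximum is exactly
10,000 and any non-zero presence scores at least 1 per axis; zero is
reserved for true absence. Where a quadrat holds several species the
package aggregates before discretizing — total coverage capped at 100% and
a coverage-weighted mean of the species' height midpoints — preserving the
index range and total-cover semantics. Lake differences and the
lake-by-period interaction are tested by permutation (`sci_lake_test()`,
`sci_interaction_test()`), permuting quadrat labels (the permutation unit
is the transect-depth quadrat; period labels are permuted within lakes for
the interaction). Monte-Carlo p-values use the add-one correction; an
exhaustive mode enumerates all assignments for small groups. Gillnet
catches are standardized by `cpue()` to fish (NPUE) and kg (BPUE) per
1000 m² net per night.

## Trophic ecology and growth

`littoral_reliance()` is the two-source δ¹³C mixing model: LR =
(consumer − pelagic) / (littoral − pelagic), with littoral macrophytes or
benthic algae and pelagic particulate organic matter as end-members.
End-members closer than 0.5 per mil make the model unidentifiable and raise
an error. Estimates outside [0, 1] are reported unclipped with a flag —
excluding an isotopically extreme individual is an analyst decision, not an
automatic one. No trophic fractionation offset is applied by default
(consumer scale tissue is compared directly to the end-members), but a
configurable offset exists. End-member summaries, where several source
samples exist, should use the mean (the package takes the values as given).

`fraser_lee()` back-calculates length-at-age from scale annulus radii,
L_i = c + (L_c − c)·S_i/S_c, with the biological intercept `c` a required
population constant — no default is invented. Where three scales are read
per fish, `average_scales()` back-calculates each scale and averages the
*lengths* per annulus (averaging radii first is available as an option;
the phrase "results were then averaged" is ambiguous, and averaging after
back-calculation keeps each scale's own proportionality).
`last_increment()` extracts the growth increment of the year before
tagging, the increment most relevant to behaviour in the study year.

## Repeatability and rank consistency

`variance_components()` decomposes a trait into between- and
within-individual variance by one-way method-of-moments ANOVA (unbalanced
designs use the standard n₀ coefficient; negative moment estimates truncate
at zero), and `repeatability()` forms R = V_between / (V_between +
V_within). The field-standard alternative is a REML mixed model with an
ARMA residual process; the ANOVA estimator is used here because it is
closed-form, dependency-free and exactly testable, and `repeatability()`
consumes externally fitted variance components (e.g. from a published
mixed-model table) unchanged. Without an autocorrelation adjustment the
ANOVA estimator can overstate the effective within-individual sample size
for strongly autocorrelated daily traits; this is a known limitation.
`rank_consistency()` complements R with Spearman rank correlations of
per-individual monthly means between month pairs (average ranks for ties,
pairwise-complete individuals, pairs with fewer than three shared
individuals skipped).

`recovery_experiment()` validates the estimator: it simulates Gaussian
daily values with a known intraclass correlation (between-individual
variance = ICC, within = 1 − ICC) and measures bias and RMSE of the
estimate. It deliberately simulates at the trait level — the trajectory
simulator has no ICC dial — so it validates the variance decomposition,
not the tracking pipeline.

## The synthetic lakes and what they do (not) emulate

Two presets reproduce the study system's structure: `scenario_hsc()` (25 m
deep, 252 ha, macrophytes covering 60–91% of 0–12 m inshore areas) and
`scenario_lsc()` (75 m deep, 311 ha, sparse 0.1–1.6% cover at 0–3 m).
`make_lake()` builds a radially symmetric paraboloid basin on a 10-m
raster — deliberately idealized; the shoreline is a circle, so boundary
effects are smooth. The thermocline declines linearly from 6.5 m (early
June) to 9.5 m (late September).

Movement (`simulate_track()`, compiled step loop) uses the simplest
standard models for the two foraging modes the literature describes
qualitatively: ambush fish follow an Ornstein–Uhlenbeck mean-reverting walk
around a home centre (σ = 0.5 m·s^−1/2, reversion 3 × 10^−4 s^−1, giving a
stationary positional SD of ~20 m), cruising fish a correlated random walk
(target speed 0.3 m/s, wrapped-normal turning with SD 0.4 rad per 25-s
step). Depth follows an autoregressive pull toward the local bottom minus
1 m (benthic) or the thermocline (pelagic), with cruising fish switching
between the two targets as a two-state Markov process — mirroring the
observed concentration of open-water positions around the thermocline.
Boundaries are reflective, which keeps tracks in-lake without resampling
bias. No published speeds or home-range scales exist for the two modes;
these presets were chosen once as ecologically plausible for an 80-cm
ambush predator and are tuned only to preserve the qualitative contrast
(cruise > ambush in space use and activity), never to match printed trait
magnitudes.

Observation (`observe_track()`) emulates the acquisition process: one
candidate burst per 25 s; detection probability decaying with depth
(0.85·e^(−depth/30)); positioning probability, separate and lower
(0.5·e^(−depth/15)), because depth needs one receiver but a position needs
three; hourly dead zones with probability 0.15 emulating correlated
coverage gaps; Gaussian position (3 m) and depth (0.1 m) noise; and the
35-m sensor ceiling. Under these defaults most intervals carry at least a
depth reading while positionable fixes thin out with depth, echoing the
field situation where depth series were much denser than positions. Not
emulated: receiver-geometry
(TDOA) error structure, prey fields, bioenergetics, or hydrodynamics —
so passing tests demonstrate the pipeline's correctness and the qualitative
behavioural contrast, not quantitative agreement with any real lake.

## Numerical choices and problem sizes

Determinism: every generator consumes one seed and identical seeds give
bit-identical output. The KUD neglects kernel mass beyond five bandwidths
of the data (< 10^−6 relative); the 1-D kernel grid extends four bandwidths
beyond the data range at 0.05-m resolution, so dV-KS is quantized to
0.05 m. Highest-density sets include the cell that crosses the target mass,
so reported areas err on the inclusive side by at most one cell. Strict
inequalities are used exactly where the rules state them (interpolation
conditions, the "more than 12" availability rule); the open-water rule is
inclusive at 5 m. Degenerate inputs: single-point days return the one-cell
KUD area; fewer than two depths give no dV-KS; empty filter input is empty
output, not an error.

The packaged experiments use 15 fish per mode for 30 days (the cohort size
and a representative span of the field season) with 40 seeded replicates
for the behavioural contrast, and 15 individuals × 100 days × 50 replicates
at ICC 0.2/0.5/0.8 for repeatability recovery; these sizes give stable
Monte-Carlo summaries while keeping the full suite runnable on a single
CPU in minutes.

```{r example, eval = FALSE}
# one fish, three days, end to end
scn <- scenario_hsc()
lk <- make_lake(scn)
f <- fish_spec("pike_01", body_length = 80, movement_mode = "ambush",
               home_center = c(500, 0))
t0 <- as.POSIXct("2015-06-01", tz = "UTC")
truth <- simulate_track(lk, f, t0, t0 + 3 * 86400, seed = 1)
fixes <- observe_track(truth, observation_model(), seed = 2)
tw <- make_twilight(seq(as.Date("2015-05-31"), by = 1, length.out = 5))
traits <- run_pipeline(fixes, lk, tw, body_length = c(pike_01 = 80))
traits
```
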