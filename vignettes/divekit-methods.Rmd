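---
title: "divekit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{divekit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(divekit)
```

`divekit` analyses satellite-relayed dive records of first-year southern
elephant seals: broken-stick abstraction of 1-Hz depth profiles,
drift-dive filtering for buoyancy (body-condition) estimation, trip-phase
delineation, and aerobic-dive-limit analyses. Because real deployments of
this kind cannot be rerun at will, the package ships a synthetic trip
generator with known ground truth; every stage of the pipeline is
validated by recovering what the generator put in. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not establish.

## The dive-abstraction model

Satellite relay tags cannot transmit 1-Hz depth series; they compress each
dive on board with an iterative broken-stick selection: starting from the
two surface endpoints, the sample with the largest vertical distance from
the current piecewise-linear reconstruction is retained, repeatedly, until
a fixed number of inflection points remain. `abstract_dive()` mirrors this
with 4 points / 3 segments by default, labelling the first segment descent,
the last ascent, and the interior bottom. A configurable `n_points` allows
richer summaries, which are collapsed back to the three roles by a rate
rule (leading segments sinking faster than 0.1 m/s are descent, trailing
segments rising faster than 0.1 m/s are ascent, remainder bottom, ties to
bottom).

Numerical conventions, fixed across the package:

* depth is positive downward (m); vertical rate is positive upward (m/s),
  so sinking is negative — matching the drift-rate sign convention;
* time and depth are kept in seconds and metres internally; minutes appear
  only at the reporting boundary, which prevents silent unit mixing;
* the reported maximum depth is the raw profile maximum, never the
  reconstruction's;
* profiles shorter than 10 samples or never exceeding 15 m are rejected as
  non-dives (15 m is the usual time–depth-recorder surface threshold);
* broken-stick ties go to the earliest sample, making the selection
  deterministic;
* accelerometer summaries (swimming-effort sums, PrCA seconds) are
  apportioned onto abstracted segments by duration-weighted time overlap,
  which conserves their totals to machine precision.

The greedy selection is checked in the test suite against an exhaustive
minimax search over all interior point pairs. The equivalence is exact for
noise-free piecewise-linear profiles (the optimum is the unique zero-error
corner pair, which the greedy pass finds); with additive noise the two
criteria can legitimately select different near-tied samples, so the
equivalence fixtures are random noiseless trapezoids. On realistic wiggly
bottoms the greedy points may land mid-bottom rather than at a corner;
this only redistributes transit effort between adjacent segments and does
not affect the drift filter (drift segments are generated without
wiggles).

## Drift filtering and the condition series

A drift dive contains a prolonged passive phase in which the seal neither
swims nor forages; its vertical rate is the buoyancy signal.
`drift_estimates()` applies five rules in order: (1) drop the first and
last segments (the active descent and the swim back up); (2) drop segments
with any PrCA; (3) drop segments with swimming-effort rate above 4 m/s³
(the empirical effort distribution is bimodal, passive vs active);
(4) drop vertical rates outside [−0.3, 0.6] m/s, and null rates (|rate| <
1e−6 m/s, a tolerance the source filter leaves unstated — such segments
are read as resting on the sea floor); (5) drop segments lasting less than
40% of the dive. The five rules are conjunctive, so their order cannot
change which segments survive; the order only affects the per-step drop
counts that the pipeline logs for provenance. If several segments survive
(possible only with >3-segment abstraction), their duration-weighted mean
is returned. The remark that drifts typically start below 65 m is treated
as rationale, not a rule; an optional `min_depth` in
`drift_filter_control()` enforces it when wanted.

Daily condition series are per-day medians of the drift estimates (days
without estimates stay missing) smoothed by a centred 7-day rolling median
requiring at least 3 daily values in the window. Medians were chosen over
means end to end because occasional mis-identified segments enter as
outliers, not as Gaussian noise.

## Trip phases, the buoyancy switch, slopes, BMI

`segment_phases()` works on the smoothed series: the departure phase ends
at its global minimum; the central phase ends at the subsequent maximum,
accepted only if the series later declines by at least 0.02 m/s (this
threshold suppresses noise-driven phantom return phases and is
configurable); the buoyancy switch is the first day after the trough with
positive smoothed drift rate. Searching for the switch after the trough,
rather than from day 0, matters because most juveniles depart positively
buoyant — the switch of interest is the recovery crossing, not the initial
state. Boundaries are detected per individual by default; a fixed 50/100-
day mode (`phases$mode = "fixed"`) is available since cohort-level
summaries are sometimes defined on fixed windows.

Departure-phase rates of change are ordinary least-squares lines through
the phase-1 daily values, fitted per individual (at least 10 days of
data). A full random-effects treatment (mixed models with individual
intercepts and slopes) is a deliberate methodological simplification left
out of scope: with per-individual fits the downstream correlations (e.g.
initial drift rate vs its slope) are computable without shrinkage, and the
package avoids a heavy modelling dependency for a quantity its tests can
check exactly.

BMI is the residual of an OLS regression of departure mass on length
across the cohort — independent of length by construction, summing to zero
to machine precision. With fewer than 3 individuals it is undefined; with
zero length variance it degrades to mass minus the cohort mean, with a
warning.

## ADL analyses

Theoretical ADL thresholds are inputs, not derived quantities: 6 min
(departure), 10 min (central), 18 min (return) for juveniles — the values
the cohort results are quoted against, rather than the wider 4–6 min
literature range for the first 100 days — and 28 min for adult females.
Both sets are configurable. Exceedance proportions are computed per
individual and phase, then pooled as mean ± SD across individuals.

The behavioural ADL ("the dive duration beyond which surface time inflects
upward") is operationalised as a binned two-segment continuous
piecewise-linear fit: 1-min duration bins, median surface duration per
bin, bins with fewer than 20 dives dropped (tail bins otherwise contribute
unstable medians), candidate breakpoints at interior bin edges with at
least two bins on each side, minimum-SSE selection. "No detectable bADL"
is declared when the best two-segment fit reduces the SSE by less than 10%
relative to a single line, or when the upper slope does not exceed the
lower one — a parsimony rule chosen over an invented significance test.
Extended surface durations (> 3.5 min, ~1.3% of dives) are excluded from
the breakpoint and surface-relation fits but kept in the tADL and summary
statistics. Surface-duration relations (vs dive duration, transit
swimming effort, bottom PrCA rate) are binned-median OLS slopes with
seeded bootstrap confidence intervals (1,000 resamples by default).

## The synthetic trip generator

The generator emulates the two study deployments: 20 juveniles sampled at
one recorded dive per 2 h for up to 338 days, and 9 adult females recorded
continuously (each dive begins when the previous surface interval ends)
for 2–3 months. Its defaults *are* the study conditions; they were
calibrated once — analytically where possible, then verified by running
the default pipeline — so that the full abstraction → filter → trajectory
→ ADL chain reproduces the published cohort statistics, and they are not
meant to be tuned per run.

**Body condition.** Each individual's true drift rate follows a continuous
piecewise-linear three-phase template (`condition_model()`): decline from
the initial value (positive for 17 of 20 juveniles, +0.15 ± 0.04 m/s;
negative for 3, −0.21 ± 0.02 m/s) to a trough of −0.25 ± 0.04 m/s around
day 50; recovery to a central-phase peak; final decline at 0.0035 m/s per
day. For switching individuals the zero-crossing day is drawn directly
(93 ± 15 days) and the phase-2 end derived from it by linearity, so the
switch day is a generator input. Non-switchers draw a negative peak. The
return-phase decline levels off 0.06 m/s above the trough: a first-year
seal does not keep sinking faster than it ever did on departure, and
without this floor the global-minimum rule for the departure boundary
would be ill-posed on long records. Cohort structure uses fixed counts
(8 of 20 early tag failures within 100 days, 9 of the 12 survivors
switching) rather than independent Bernoulli draws, mirroring the study
design. Adults improve condition linearly from −0.27 m/s without becoming
positive.

**Dives.** Profiles are trapezoids: constant-rate descent and ascent at
1.0–1.5 m/s and a bottom with small sinusoidal depth wiggles (amplitude
≤ 3 m) that start and end on the bottom line. Target depth follows the
ontogeny curve — ~60 m at departure, 115 ± 21 m at day 50, 227 ± 50 m at
month 8 (day 240), then flat; adults are stationary at 474 ± 79 m. Bottom
time is drawn (SD 5 min) and duration *emerges* as transit + bottom, so
deeper dives last longer; the day's expected duration stays on the
ontogeny mean (9.5 min at departure rising to 15.5 min by day 180 around
a 12.5-min midpoint; adults stationary at 18.5 min). Drawing duration
independently of depth and truncating, the obvious alternative, enriches
long durations with deep dives and manufactures a spurious surface-
duration kink — an artefact, not a behaviour. With probability 0.10 a
dive is a drift dive: the bottom is replaced by a passive segment at the
true drift rate plus noise (SD 0.02 m/s), occupying ≥ ~45% of the dive,
starting below 70 m but capped at 300 m (drift dives are rest/digestion
dives at mid-water depths, not at the foraging depth — uncapped, deep
adult drift dives dominate the long-duration tail and again fake a bADL).
The drift fraction of recorded dives is not reported for either age class
in the source material; 0.10 is a stated guess, exposed as
`drift_dive_prob`.

**Effort, PrCA, surfacing.** Active segments carry effort rates of
6 + 10·|DR| m/s³ (SD 0.5) — buoyancy deviation costs swimming effort —
while passive segments draw 0.5–2.5 m/s³, placing the two modes on either
side of the 4 m/s³ filter threshold. Bottom PrCA fractions average 0.10
for juveniles early in the trip, decaying to the adult level of 0.05 by
day 100. Surface duration is `0.76 min + 2.1e-4 · (transit effort sum) −
1.0 · (PrCA rate)` plus noise (SD 0.15 min), floored at 30 s; with
probability 0.013 it is replaced by an extended surface (> 3.5 min).
The two coefficients were solved from the juvenile and adult mean surface
durations (1.15 and 2.0 min) given the expected transit efforts of each
age class; the PrCA term encodes the observed shortening of recovery
after successful foraging.

**Attrition and haul-outs.** Tag-failure individuals truncate at a day
drawn uniformly on [15, 100]; survivors monitor until a uniform day on
[150, 338] (adults [60, 90]). Surviving juveniles haul out once, 15–40
days after the condition peak (the return transit spans weeks); haul-out
duration is keyed to the buoyancy sign at return — 8.7 ± 4.4 days if
positive, 2.9 ± 2.59 if negative — and dives are suppressed during the
haul-out.

**Randomness.** One master seed drives everything. Each individual uses a
derived sub-stream (`individual_seed()`), so enlarging the cohort never
reshuffles earlier individuals; identical parameters and seed give
bit-identical records, which the tests verify by serialisation.

**Fidelity limits.** The generator produces what the pipeline needs and no
more. It does not emulate: geographic movement, bathymetry or the
benthic/pelagic habitat split; 16-Hz accelerometry (segment-level effort
and PrCA sums are emitted directly, standing in for the tag's on-board
processing); autocorrelated residuals or individual heterogeneity beyond
the template offsets; diel behaviour; transmission gaps other than whole-
record truncation. Passing recovery tests on these records therefore shows
the pipeline is a faithful implementation of the stated rules and is
unbiased under the stated noise model — it does not certify performance on
real tag data, whose failure modes (depth spikes, partial summaries,
misaligned accelerometer windows) are upstream of this package's scope.

## Problem sizes and the fast path

`simulate_cohort(level = "segment")` emits the abstraction-equivalent
segment tables directly, skipping 1-Hz synthesis; for noise-free
piecewise-linear profiles the two paths coincide (the abstraction-fidelity
tests establish this), so large-replicate recovery studies — filter-oracle
equivalence on 10⁴ random dives, switch-day recovery over 100 simulated
juveniles — use the fast path. Cohort-statistic validation always runs the
full 1-Hz route: both default cohorts (~3.7 × 10⁴ juvenile and ~4.5 × 10⁴
adult dives) simulate, abstract and analyse in a few minutes on one core.
The end-to-end report is byte-identical across repeated runs at a fixed
seed, including the bootstrap.

## Known limitations

* Only one haul-out per record is modelled, and condition is not reset by
  it; multi-trip records share a single template.
* The bADL negative finding depends on the 10% SSE-gain parsimony rule;
  a likelihood-based changepoint test would give it an inferential basis.
* Per-individual OLS slopes understate between-individual shrinkage
  relative to the mixed-model treatment they replace.
* The 0.10 drift-dive probability is a guess (see above); daily drift
  coverage — hence switch-day detection error — scales directly with it.
* Segment-level PrCA is a fraction of bottom time; no within-segment event
  structure is represented.
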