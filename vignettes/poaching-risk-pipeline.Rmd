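---
title: "From collar fixes to poaching risk: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From collar fixes to poaching risk: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`poachrisk` is a pipeline for conservation informatics built around a single
question: given a GPS-collared animal's movement history, will it soon be
dangerously close to a known hazard site?  The package chains five stages:

1. **Observations.** A table of collar fixes (date, time, latitude,
   longitude plus ancillary sensor columns), either read from a collar CSV
   export or produced by the package's own movement simulator.
2. **Knowledge graph.** The table is mapped to RDF triples under the Forest
   Observatory Ontology (`foo:`) and the W3C WGS84 geo vocabulary: one
   `foo:gPSObservation` node per fix carrying `geo:latitude`,
   `geo:longitude`, `foo:localDate` and `foo:localTime` literals, linked to
   a sensor node and a feature-of-interest (animal) node.  Hazard sites are
   `foo:OilPalmPlantation` nodes with coordinates.
3. **Forecasting.** Observation rows are extracted back out of the graph,
   encoded as calendar features, and used to train a sequential neural
   network that predicts future coordinates; three classical baselines
   (linear, polynomial, vector autoregression) are fitted for comparison.
4. **Rule-based reasoning.** Predictions are re-inserted into the graph as
   observation nodes, and a distance rule asserts a binary `foo:poaching`
   indicator on every observation: 1 when the haversine distance to the
   plantation is within 5 km (inclusive), 0 otherwise.
5. **Reporting.** A CONSTRUCT-style subgraph per flagged observation, a
   Turtle serialization of the full graph, a GeoJSON buffer ring, an RMSE
   comparison table and a JSON run manifest.

## The geofence rule

The rule's core is the haversine great-circle distance on a sphere of mean
Earth radius $R = 6371$ km,

$$a = \sin^2\!\frac{\Delta\phi}{2} +
      \cos\phi_1\cos\phi_2\,\sin^2\!\frac{\Delta\lambda}{2}, \qquad
  d = 2R\,\arcsin\sqrt{a},$$

with an *inclusive* threshold: `poaching = 1` iff $d \le r$, with $r = 5$ km
by default.  The inclusive comparison is part of the rule's semantics and is
deliberately not configurable; only the radius is.  Two numerical details
matter.  Longitude differences are wrapped to $[-180^\circ, 180^\circ]$
before differencing, because the raw haversine formula is wrong across the
antimeridian (the study region near 118° E never triggers this, but the
function is general).  The quantity $a$ is clamped to $[0, 1]$ so antipodal
rounding cannot produce `NaN`.  The equivalent
$\mathrm{atan2}(\sqrt{a},\sqrt{1-a})$ form is algebraically identical for
$a \in [0,1]$ and is not implemented separately.

Buffer rings for map export place vertices with a local equirectangular
approximation and then validate every vertex by the haversine distance
(tolerance 0.1%); at a 5 km radius and 5° N the projection error is below
0.01%, orders of magnitude under the tolerance, so an exact spherical
destination formula would add complexity without measurable benefit.

## The movement simulator

Real single-animal collar datasets from this region are sensitive and not
redistributable, so the package ships a generator whose *defaults* emulate
the published statistical profile of such a deployment: 9,168 fixes at a
2-hour cadence starting in 2012, latitudes clamped to [5.01, 5.38],
longitudes to [118.44, 118.95], collar temperature N(29.2, 1.93²) °C, and
the ExtTemp/Activity/Speed/Direction columns all zero (as in the collar
export being emulated), with a flag to populate them.

Movement is modelled in local east/north kilometres about a home centre as
the sum of:

* a **diurnal foraging loop** of radius 2 km (period 24 h) — elephants
  commute between feeding and resting areas on a daily rhythm;
* a **seasonal drift** of the range centre along the longitude axis,
  amplitude 8 km, annual period — a stand-in for seasonal range shifts;
* an **autoregressive (Ornstein–Uhlenbeck-style) jitter** with per-step
  persistence 0.95 and stationary SD 3 km, pulling the animal back toward
  the (moving) centre;
* optional **excursions**: with probability 0.02 per fix the animal travels
  toward the plantation at 0.8 km/h, dwells nearby, and returns, so long
  tracks contain fixes inside the 5 km buffer.

The deterministic diurnal/seasonal structure is what makes the track
partially predictable from calendar features — the property the forecasting
stage depends on — while the jitter keeps it stochastic.  What the
generator does **not** emulate: behavioural states, habitat covariates,
terrain, GPS dropouts, or the temperature anomalies present in real collar
exports.  Tests passing on this generator therefore demonstrate that the
pipeline's machinery is correct, not that the network would achieve any
particular accuracy on real elephant data.

Amplitudes were chosen once for realism at the scale of Bornean elephant
home ranges and to approximate the published coordinate spread; they are
configuration, not tuning knobs, and the parameter-recovery tests (lag-1
persistence within ±0.05, temperature mean within 3 standard errors) pin
the generator's statistical contract.

## Feature encoding and splits

Each observation becomes the integer feature vector (day, month, year,
hour); minutes carry no information at a 2-hour cadence.  Two label modes
exist because the forecasting target set is genuinely ambiguous in this
design space: mode `"latlong"` (default) predicts (latitude, longitude);
mode `"spatiotemporal"` predicts (date, time, longitude, latitude) with the
date target encoded as days since the first observation and time as seconds
since midnight ("12:34:56" → 45,296 s).  The four-target mode reports its
units explicitly rather than normalizing, so its RMSEs are directly
interpretable (days and seconds).

The chronological split is 60/20/20 of the total — the last 20% is the test
block, and the remaining 80% splits into 60% training and 20% validation of
the total.  Block sizes are `floor(n·f)` with the remainder assigned to
training.  Shuffled splits are deliberately absent from the pipeline: the
data are a time series and every evaluation must respect temporal order.
Feature standardization statistics come from the training block only;
zero-variance columns (such as the year in a short run) are centred but not
divided, with a warning; labels are never scaled, so every reported RMSE is
in native units.

## The network and its training protocol

The regressor is a fully-connected network with hidden layers of 128 and 64
rectified-linear units and a linear output layer, trained with Adam at its
canonical defaults (learning rate 0.001, β₁ = 0.9, β₂ = 0.999) for 500
epochs with batch size 32.  Validation loss is recorded every epoch but
never acted upon — there is no early stopping.  The loss is reported as
RMSE; the gradient actually followed is the mean-squared-error gradient,
which points in the same direction (RMSE is a monotone transform of MSE),
and under Adam's gradient normalization the two are practically equivalent
— this was verified empirically.

Numerical choices: hidden weights use He-normal initialization; output
weights start near zero and the output bias starts at the training-label
column means, so the network begins as the mean predictor.  This matters
because the targets are in raw degrees (longitudes near 118.7): with a
zero-initialized output layer and Adam's bounded per-step movement, the
network would spend most of its epoch budget just reaching the data's mean
level.  Training is deterministic given the configuration seed (seeded
initialization and batch shuffling), and divergence (non-finite loss)
aborts with the epoch index.

A known limitation, documented here because it shapes what short runs can
show: with only a few months of data, the chronological test block contains
calendar months never seen in training, and an unregularized ReLU network
extrapolates linearly along those feature directions.  On short tracks
(~2,000 fixes ≈ 5.5 months) this extrapolation error is of the same order
as the per-step movement of the animal, so test RMSE can sit above the
per-step displacement SD even when the trajectory is almost deterministic —
a constant-per-hour predictor does far better there.  On multi-year tracks
every month appears in training and the effect disappears.  This is a
property of the calendar feature encoding at short scale, not of the
optimizer; the test suite records it honestly rather than papering over it.

## Baselines and evaluation

* **Linear regression**: each target on the day-of-month predictor,
  evaluated with 5-fold expanding-window time-series cross-validation (fold
  *i* trains on the first *i* blocks of `floor(n/6)` rows and tests on the
  next); per-target RMSE is the mean over folds.
* **Polynomial regression (degree 4)**: the same on the raw basis
  (day, day², day³, day⁴); a rank-deficient design errors rather than being
  silently regularized.
* **Vector autoregression**: latitude and longitude as a bivariate series;
  lag order selected by AIC (OLS per equation, default maximum lag 8 = one
  day of 2-hourly fixes) on the first 80%, then an iterated multi-step
  forecast over the reserved 20% holdout.  A constant series is forecast
  exactly with RMSE 0.

The evaluation report has one row per model with per-target RMSEs and their
unweighted arithmetic mean — the table's defining identity, asserted in the
tests.  Printed summaries round half away from zero.

## Knowledge-graph semantics

No RDF toolkit ships with this R stack, so the triple container, the
Turtle 1.1 writer, and a parser for the emitted subset (prefix directives,
IRIs, prefixed names, `a`, typed and plain string literals, `;`/`,`
continuation) are implemented in the package; a test cross-checks the
serialization against an independent Python RDF parser.  The rule and the
extraction query are executed as in-process operations over the triple
table with the same semantics as their SPARQL forms (shipped under
`inst/sparql/` as query assets): the extraction is a basic graph pattern,
so observations missing any of the four properties are skipped (and
counted in a warning); the rule replaces existing `foo:poaching` flags
instead of duplicating them, making re-application idempotent, and errors
if no plantation node is present rather than silently matching nothing.
Re-applying the rule after inserting predictions recomputes all flags —
the simplest consistent semantics.  The rule runs over historical *and*
predicted fixes alike; predicted fixes are ordinary observation nodes plus
one provenance triple in an extension namespace.

Coordinate literals are written as the shortest decimal string that parses
back to the identical double, so a table that travels
CSV → graph → extraction returns bit-exact coordinates.  Literal datatypes:
coordinates `xsd:float`, dates `xsd:date`, times `xsd:time`, poaching flags
`xsd:integer`.  Observation IRIs are deterministic
(`foo:observation_<obs_id>`), so rebuilt graphs are reproducible.

## Problem sizes used in the test suite

The shipped tests run the simulator at 100–9,168 fixes, the network at 5 to
500 epochs on 200–2,000 fixes, randomized property checks at 500–1,000
cases, and the full pipeline at 300–400 fixes; these sizes keep the whole
suite in the tens of seconds while still exercising every contract at
realistic scale.  The full-scale protocol (9,168 fixes, 500 epochs) is
available by simply passing the default configurations.

## Worked example

```{r, eval = FALSE}
library(poachrisk)

cfg <- pipeline_config(
  sim_config = trajectory_config(n_obs = 2000, seed = 7),
  plantation = c(latitude = 5.25, longitude = 118.70),
  mlp = mlp_config(epochs = 100, seed = 7),
  horizon_steps = 12,
  output_dir = "run", seed = 7)
res <- run_end_to_end(cfg)
res$evaluation
res$manifest$counts
autoplot(simulate_trajectory(cfg$sim_config),
         plantation = cfg$plantation)
```
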