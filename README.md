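# poachrisk

Poaching-risk inference from GPS-collar telemetry, for movement ecologists
and conservation informaticians.  The package implements an end-to-end
pipeline: collar observation tables (real CSV exports or simulated tracks
with the statistical profile of a Bornean-elephant deployment) are mapped
into an ontology-based RDF knowledge graph (Forest Observatory Ontology +
W3C WGS84 geo vocabulary); observation rows are extracted back out, encoded
as calendar features and used to train a sequential neural network that
forecasts future geo-locations (benchmarked against linear, polynomial and
vector-autoregression baselines); the predictions are re-inserted into the
graph; and a rule asserts a binary poaching indicator on every observation
from its great-circle distance to a hazard site (an oil-palm plantation).

The rule's core is the haversine distance on a sphere of mean Earth radius
R = 6371 km,

    a = sin²(Δφ/2) + cos φ₁ · cos φ₂ · sin²(Δλ/2)
    d = 2R · asin(√a)

with `poaching = 1` iff `d ≤ r` (inclusive; `r` = 5 km by default).  The
forecaster is a fully-connected network (hidden layers 128 and 64, ReLU,
linear output) trained with Adam on an RMSE objective for 500 epochs with
batch size 32 on a chronological 60/20/20 train/validation/test split; all
RMSEs are reported per target and as their unweighted mean.

Everything is tibble-first and pipe-friendly: observation tables, triple
graphs and evaluation reports are tibbles, fitted models have `tidy()`,
`glance()` and `autoplot()` methods, and the whole pipeline is one
`run_end_to_end()` call.

## Worked example

```r
library(poachrisk)

cfg <- pipeline_config(
  sim_config  = trajectory_config(n_obs = 2000, seed = 7),
  plantation  = c(latitude = 5.25, longitude = 118.70),
  mlp         = mlp_config(epochs = 100, seed = 7),
  horizon_steps = 12,               # forecast one day ahead at 2-h cadence
  output_dir  = "run", seed = 7)
res <- run_end_to_end(cfg)
res$evaluation
#> # A tibble: 4 × 4
#>   model                 latitude longitude average
#>   <chr>                    <dbl>     <dbl>   <dbl>
#> 1 Sequential NN           0.0553    0.0638  0.0596
#> 2 Linear Regression       0.0289    0.0333  0.0311
#> 3 Polynomial Regression   0.0298    0.0345  0.0322
#> 4 VAR Model               0.0297    0.0299  0.0298
str(res$manifest$counts)
#> List of 8
#>  $ observations        : int 2000
#>  $ triples_initial     : int 14005
#>  $ rows_extracted      : int 2000
#>  $ predictions         : int 12
#>  $ poaching_annotations: int 2012
#>  $ poaching_positive   : int 702
#>  $ report_triples      : int 10060
#>  $ triples_final       : int 16089
```

Reading the output: each model's `latitude`/`longitude` columns are
test-block RMSEs in decimal degrees (0.01° ≈ 1.1 km here), and `average` is
their arithmetic mean.  The counts show conservation across stages — 2,000
CSV rows become 2,000 observation nodes and 2,000 extracted feature rows;
the 12 forecast fixes are inserted back, so 2,012 observations receive a
poaching flag (702 of them inside the 5 km buffer on this simulated track),
and the report subgraph holds five triples per flagged observation.  The
output directory contains `observations.csv`, `graph.ttl`, `report.ttl`,
`evaluation.csv`, `buffer.geojson` and `manifest.json`.

Individual stages are ordinary functions if you want only a piece:

```r
obs   <- simulate_trajectory(trajectory_config(n_obs = 500, seed = 1))
graph <- map_observations_to_graph(obs) |>
  add_plantation(5.25, 118.70) |>
  apply_poaching_rule(radius_km = 5)
construct_poaching_report(graph)
haversine_km(5.20, 118.66, 5.25, 118.70)
#> [1] 7.108418
```

A thin command-line wrapper with `simulate`, `build-kg`, `reason`, `report`
and `run-all` subcommands lives at `inst/scripts/poachrisk`.

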