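# paircohesion

Spatial pair cohesion from automated radio-tracking arrays.

Territorial, socially monogamous birds — how tightly do partners actually
cohere in space, during and after breeding? Fixed grids of radio receivers
answer this at 15-second resolution: each receiver logs the tag id, the
received signal strength (RSS, negative dB) and the time of every beacon
it hears. `paircohesion` is the full analysis pipeline from those raw
detection logs to pair-cohesion statistics, for movement ecologists
working with receiver-grid ("node") telemetry:

1. **Calibration** — fit the RSS–distance law
   `d(RSS) = 10^(a + b·RSS)` m by OLS on calibration walks; with the
   field-calibrated coefficients (a = −1.27009, b = −0.03302) the −80 dB
   cutoff corresponds to a 23.5 m detection radius. Height-effect metrics
   quantify how ground-level tags vanish from the array.
2. **Localization** — per half-open, epoch-aligned 15-s window, by the
   *strongest-detection* method (tag at the receiver with maximum RSS
   ≥ −80 dB) and by *multilateration* (≥3 receivers; 100 resampled
   distance draws on the log10 scale, each solved by bounded nonlinear
   least squares; mean of fits plus a bivariate-normal error ellipse),
   with localization-rate and gap diagnostics.
3. **Coverage** — detectable-area arithmetic (n·πr² summed and true disk
   union), minimum convex polygons, and the expected localization
   fraction of a use polygon.
4. **Home range & overlap** — gridded utilization distributions (Gaussian
   kernel, per-cell mass), 95% isopleth areas per individual × week ×
   section of day, and Bhattacharyya overlap
   `BC = Σ√(p·q) ∈ [0, 1]` for pair-bonded vs non-pair dyads.
5. **Cohesion** — pairwise separation against a *day-shift null* (partner's
   track from day x+1 at the same time of day), movement-event and
   following-event detection on the receiver vocabulary, the
   90th-percentile (nearest-rank) lag threshold, following rates, and
   initiation attribution.
6. **Synthetic generator** — receiver grids, coupled Ornstein–Uhlenbeck
   pair movement with leader/follower role switching, and distance- and
   height-dependent detection emission, so every statistic above is tested
   as a ground-truth recovery problem.

## Worked example

Simulate a one-pair tracking day, localize it, and measure cohesion:

```r
library(paircohesion)

sc  <- simulate_scenario(n_pairs = 1, n_days = 1, day_hours = 6,
                         movement = movement_config(coupling = 0.8),
                         seed = 1)
est <- localize_strongest(window_detections(sc$detections), sc$array)
la  <- est[est$tag_id == "P1F", ]; lb <- est[est$tag_id == "P1M", ]

st <- separation_series(la, lb, mode = "true")
sn <- separation_series(la, lb, mode = "null")   # needs >= 2 days; empty here
ev   <- extract_movement_events(la)
cand <- extract_following_events(ev, lb)
thr  <- lag_threshold(cand)
following_rate(ev, cand, max(thr, 15), la, lb)
```

The full workflow lives in `analysis/01_simulate.R` …
`analysis/05_cohesion.R` — thin drivers over the package functions that
write their tables under `results/`. On the default 3-pair, 3-day scenario
(seed 42) they print, among others:

```
fitted curve vs generating coefficients:
  intercept -1.24520 (generated -1.27009)
  slope     -0.03267 (generated -0.03302)
  -80 dB radius: 23.4 m
detection rate elevated 0.821 vs ground 0.094 (ratio 8.7)
multilateration (P1F, day 1): 498 fixes, rate 0.35, median error 9.3 m
overall: pair-bonded BC 0.79 vs non-pair 0.00
separation distances, true vs day-shift null (m):
 pair_id  mean_true_m mean_null_m same_receiver_frac
      P1         13.7        61.2              0.791
```

Read: the calibration walk recovers the generating law; near-ground tags
are detected ~8× less often; multilateration is accurate to ~10 m on this
geometry; pair-bonded birds share almost identical home ranges while
non-pair dyads barely overlap; and true pair separation (≈14 m) sits far
below the independent-movement null (≈61 m) — the three signatures of
pair cohesion the pipeline is built to measure.

## Layout

```
R/                  package code (calibration, localization, coverage,
                    homerange, cohesion, simulate, scenario, io)
analysis/           numbered workflow drivers writing results/
scripts/acceptance.R
tests/testthat/     unit, property, and acceptance test suites
vignettes/          methods vignette (model, conventions, design choices)
```
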