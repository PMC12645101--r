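---
title: "Methods: from raw beacon detections to pair-cohesion statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw beacon detections to pair-cohesion statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paircohesion)
```

## The problem

Automated radio-tracking grids record, every few seconds, which fixed
receivers heard which tag and how strongly (received signal strength, RSS,
a negative dB value; closer to 0 means a stronger signal and a shorter
tag–receiver distance). From those raw detections this package
reconstructs where each bird was, how much space it used, and — the
question the pipeline exists for — how tightly pair-bonded birds of a
territorial, socially monogamous passerine cohere in space: shared home
ranges, sustained proximity, and active following of a moving partner,
both during and after breeding.

Every stage is exercised against a synthetic generator with known ground
truth, so each statistic can be validated as a *recovery* problem: the
generator plants a coupling, a territory size, or a height penalty, and
the pipeline must find it.

## Calibration: the RSS–distance law

Distance decays log-linearly in RSS:

$$ d(\mathrm{RSS}) = 10^{\,a + b\,\mathrm{RSS}} \quad\text{(meters)} $$

with field-calibrated coefficients $a = -1.27009$, $b = -0.03302$
(`reference_curve()`), under which the $-80$ dB signal cutoff corresponds
to a 23.5 m radius around a receiver. `fit_calibration()` estimates the
law by ordinary least squares of $\log_{10} d$ on RSS, pooled over tags
and receivers into one global curve. The regression direction deserves a
note: calibration walks *measure* RSS at known distances, so noise sits in
the regressor; we nevertheless fit distance-on-RSS because that is the
form in which the law is applied (RSS in, distance out), and the
attenuation this induces is small relative to the tolerance of everything
downstream (with 2 dB RSS noise over the 1–200 m ladder the slope bias is
about 1%). The residual standard error on the $\log_{10}$-meter scale is
retained on the curve object: it is the spread that the multilateration
resampler draws from.

Tag height matters enormously for detection: the generator's emission
model multiplies detection probability by a ground-height penalty (default
$1/8.3$) while leaving RSS itself untouched, reproducing the field
observation that near-ground tags are detected an order of magnitude less
often but, when detected, at similar signal strength.
`point_detection_metrics()` summarizes stationary test-point trials (rate,
receiver count, mean/max RSS per point and height); undetected points
carry missing RSS summaries, never zeros.

## Localization

Detections are collapsed into half-open, epoch-aligned 15-second windows
(`floor(t/15)*15`), keeping each receiver's strongest detection per
window. Epoch alignment is a deliberate choice the source protocol leaves
open: it makes windows comparable *across* tags, which every dyadic
statistic downstream requires.

Two localizers operate on the windowed table:

* **Strongest detection** — the tag sits at the coordinates of the
  receiver with the maximum RSS, provided that maximum meets the $-80$ dB
  cutoff. Exact ties break to the lowest receiver id (deterministic,
  order-invariant). Estimates are therefore quantized to receiver
  locations, which is exactly what makes receiver identity usable as a
  shared "location vocabulary" for the following-behavior analysis.
* **Multilateration** — for windows with at least 3 above-threshold
  receivers, per-receiver distances are resampled 100 times as
  $10^{\mathcal{N}(a + b\,\mathrm{RSS}_i,\ \sigma_{\mathrm{res}})}$ —
  Gaussian on the $\log_{10}$ scale, because that is the scale on which
  the law was fitted — and each draw is solved by bounded nonlinear least
  squares on $\sum_i (\lVert p - r_i\rVert - d_i)^2$ (L-BFGS-B with
  analytic gradient, initialized at the proximity-weighted receiver
  centroid, bounded by the array box expanded 200 m). The reported
  location is the mean of the converged fits; whether the original
  analysis reported the mean of fits or the fit at mean distances is not
  stated, and mean-of-fits was chosen because it is the quantity whose
  spread the ellipse summarizes. The error ellipse takes the sample
  covariance $\Sigma$ of the fit cloud and reports semi-axes
  $\sqrt{2\lambda_i}$ with the leading-eigenvector orientation — a
  concrete reading of a "square root of two-sigma" bivariate-normal
  ellipse; the coverage interpretation of that phrase is ambiguous, so the
  convention is documented here rather than asserted as the original one.
  Iterations that fail to converge are dropped; a window keeping fewer
  than half its iterations yields no estimate. With zero residual spread
  the resampling collapses and the ellipse degenerates to a point, which
  the tests assert.

Yield diagnostics follow the standard presentation: the localization rate
is localized 15-s slots over all daylight slots between a tag's first and
last fix, and gaps are maximal runs of unlocalized daylight slots, split
at sunset/sunrise so a night never masquerades as one long gap. Daylight
is supplied as a per-date sunrise/sunset table; no solar geometry is
computed.

## Coverage arithmetic

With the strongest-detection method a bird is only localizable within the
cutoff radius of some receiver, so the *expected* yield is a geometry
question. `detectable_area()` reports both the conventional summed
arithmetic ($n \pi r^2$, which double-counts overlap) and the true union
of disks (rasterized at 0.5 m). For a 94-receiver array and $r = 23.5$ m
the summed area is 0.16 km², i.e. 12.59% of a 1.27 km² array *under the
conventional rounded-input presentation*: 0.16/1.27 truncated at two
decimals. Exact arithmetic gives 12.84%; the report exposes both values
rather than resolving the discrepancy. Use polygons are classical minimum
convex polygons (`grDevices::chull`), with the 95% variant peeling the 5%
of points farthest from the centroid; disk–polygon intersections use
64-gon circle approximations (area error below 0.2%) clipped by
Sutherland–Hodgman against the convex hull. No planar-geometry dependency
is used; these are small, tested primitives.

## Utilization distributions and overlap

Space use is summarized as a gridded utilization distribution (UD):
Gaussian kernel density (via `MASS::kde2d`) converted to per-cell mass and
renormalized, on 10 m cells by default. The bandwidth is Silverman's
rule-of-thumb per axis. This is a deliberate, documented stand-in for
autocorrelated kernel density estimation (AKDE): continuous-time movement
modelling, variogram checking and AICc selection are out of scope here,
and the statistics built *on top of* the UD — the 95% isopleth area and
the Bhattacharyya coefficient — are preserved exactly. Fixed-bandwidth KDE
under-smooths autocorrelated tracks relative to AKDE, so absolute area
values are not comparable to AKDE areas; recovery tests therefore anchor
on closed forms (for an isotropic Gaussian the 95% area is
$\pi\sigma^2\chi^2_{0.95}(2) \approx 5.99\pi\sigma^2$, recovered within
15%) rather than on field values.

The home-range area at level $q$ is the area of the smallest set of cells
(greedy, descending mass) with cumulative mass $\ge q$; "95% home range"
is read as the 95% isopleth, the standard meaning, rather than a
confidence interval. Overlap between two UDs on aligned grids is the
Bhattacharyya coefficient $\mathrm{BC} = \sum_c \sqrt{p_c q_c} \in [0,1]$,
symmetric and invariant to common grid refinement. Dyads are every
unordered pair of tagged individuals, labelled pair-bonded when metadata
assigns both to one pair — 12 individuals yield 66 dyads.

Estimates are split by week (7-day blocks from a configured start date),
section of day (hours post sunrise in $[0,3)$, $[3,6)$, $[6,9)$,
$[9,14)$; later fixes fall in section 4 with a warning, pre-sunrise fixes
in section 1 with a warning) and breeding period (before/after a
configured end date). Splits with fewer than 10 estimates — the KDE
minimum — are skipped.

## Pair cohesion

**Proximity.** The true separation series matches the two birds' estimates
on identical windows. The null series asks how close the pair would be if
each bird simply ran its own daily routine: bird A on day $x$ is matched
to bird B on day $x{+}1$ at the same time of day (exactly $+86400$ s, so
the time-of-day structure is preserved); days without partner data drop
out. A day-shifted empirical null is preferred to trajectory simulation
precisely because it keeps every idiosyncrasy of real movement except the
momentary coordination.

**Movement events.** On the strongest-method series, a movement event is a
change of receiver between consecutive *localized* windows with both
endpoint detections above $-80$ dB. Gaps are skipped rather than breaking
events, because unlocalized windows are pervasive in this kind of data and
treating each gap as an event boundary would discard most genuine
relocations; the cost is that depart/arrive times are the observed
bracketing windows, not the unobservable true ones.

**Following events.** For a leader event $A \to B$, a candidate following
event requires the follower's most recent fix at or before the leader's
departure to be at $A$ (within a staleness limit — how long a follower may
go unobserved at $A$ is not defined by the protocol, so it is an explicit
free parameter, unlimited at extraction and available for sensitivity
checks), and the follower's own next departure from $A$ to arrive at $B$.
The lag is follower arrival minus leader arrival, clamped at zero when the
follower arrives first. Extreme lags arise from detection gaps, so a
threshold is set at the 90th percentile of candidate lags across the whole
dataset (global, not per pair), using the *nearest-rank* convention — the
$\lceil 0.9n\rceil$-th order statistic — which guarantees by construction
that at least 90% of candidates fall within the threshold. The following
rate then counts, among leader movement events where both birds were
observed within the threshold of the event, the fraction matched by a
candidate with lag at or below it; undefined rates (no eligible events)
are missing, never zero.

**Initiation.** Within maximal runs of windows where both birds share a
receiver, the bird first localized elsewhere afterwards is credited with
initiating the departure; same-window departures count as simultaneous, as
a category mutually exclusive with the directional shares (whether the
original tally treated them this way is ambiguous; here the three shares
always sum to 1).

## The synthetic generator

`simulate_scenario()` emulates the study conditions at desk scale:

* **Array** — a 10×10 grid at 115 m spacing (within the field's 100–150 m)
  with 10 m placement jitter, spanning ≈1.07 km² — a stand-in for the
  94-receiver, 1.27 km² field grid. Four extra receivers are clustered 60 m
  around each territory center, emulating the field array's preferential
  receiver placement in habitat the birds favor; without this, a territory
  confined near one receiver produces almost no receiver *changes* and the
  following analysis has nothing to work with — as in the field, where
  detection rates exceeded homogeneous-coverage expectations for exactly
  this reason.
* **Movement** — each pair member is an Ornstein–Uhlenbeck (OU) process
  around its territory center, discretized with the exact transition
  ($\phi = e^{-\Delta t/\tau}$, innovation sd
  $\sigma\sqrt{1-\phi^2}$) so arbitrarily long runs remain stationary
  (empirical sd within 10% of nominal, tested). The stationary sd defaults
  to 30 m during breeding and 85 m after, back-solved via the Gaussian 95%
  area from the reported mean home ranges (0.015 and 0.139 km²). The OU
  timescale (300 s) and follow lag (60 s) are free parameters — no
  movement-speed figures exist to calibrate them — chosen to give a small
  passerine plausible minute-scale territory traversal; they are
  documented, not fitted. At each 15 s step the follower, with probability
  `coupling` (default 0.8), relaxes toward the leader's current position
  over the follow lag plus 5 m of local noise; otherwise it follows its own
  OU dynamics. Leader/follower roles swap by a symmetric Markov chain (0.1
  per minute), so both sexes initiate movements at equal rates in
  expectation, as observed in the field.
* **Emission** — every receiver within 250 m of a beacon detects it with
  probability $p_{\max}\,\mathrm{logit}^{-1}((d_{50}-d)/w)$ (defaults 0.9,
  90 m, 30 m), times the 1/8.3 ground penalty for ground-height tags; RSS
  is the inverse calibration law at the true distance (clamped below at
  1 m, the smallest calibration distance, to avoid the log singularity)
  plus 2 dB Gaussian noise — the noise magnitude around the field curve is
  unpublished, and 2 dB keeps the fitted residual spread near the value
  that reproduces field-scale multilateration error (median ≈10–35 m).

Fixing the seed fixes every output byte for byte.

**What the generator does not emulate** — habitat heterogeneity, roosting
and night behavior, nest-attendance alternation, tag-orientation and
perch-height RSS effects, and movement autocorrelation structure beyond
OU. Passing recovery tests therefore demonstrate that the *pipeline*
measures what the generator plants under realistic geometry, noise, and
sampling gaps; they do not demonstrate that field estimates are unbiased
with respect to these unmodelled effects (the day-shift null and the
side-by-side reporting of both localization methods are the mitigations
carried over from the source design).

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: singular calibration designs
error; bandwidths that collapse (identical points) fall back to the cell
size; multilateration windows keeping under half their resamples yield no
estimate; zero-denominator rates are missing. Tests and the acceptance
script run the simulations at deliberately modest sizes — 1–3 pairs, 1–3
days of 1–14 daylight hours, 10×10 arrays, 20-seed replications for the
stochastic-ordering properties, OU stationarity at 12,000 steps — sizes at
which every recovery property is comfortably resolved while the whole
suite stays fast. The analysis scripts under `analysis/` use a 3-pair,
3-day scenario spanning the breeding split.

## Known limitations

Fixed-bandwidth KDE areas are not AKDE areas; strongest-method locations
are quantized to receiver coordinates, so separation distances below the
receiver spacing are coarse (the same-receiver fraction is the honest
statistic at that scale); multilateration error inflates separation
distances, so both methods are reported side by side; and the regression
treatment of statistical models downstream of the exported tables (GAM
smooths of rates over time of day, beta regressions on overlap) is out of
scope — the per-split tables are exported for external modelling.
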