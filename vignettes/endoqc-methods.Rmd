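---
title: "endoqc: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{endoqc: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What endoqc models

Rigid surgical endoscopes degrade in clinical use — sterilization cycles,
ionizing radiation and mechanical stress slowly damage both of their
optical pathways: the fibre bundle that carries illumination to the tip,
and the rod-lens train that relays the image back to the eyepiece. Because
that degradation is gradual and hard to judge by eye, quality assurance
benches measure two numbers per instrument per session:

* **Transmission** of the illumination pathway, in calibrated units.
  A photocell first reads the light source directly (the *calibration
  signal*, defining full scale = 100 units), then reads the light arriving
  through the endoscope's fibres. The reported value is
  $100 \cdot S_\mathrm{endo} / S_\mathrm{cal}$.
* **Contrast** of the viewing pathway, in grey levels. Black/white line
  patterns at seven spatial frequencies are displayed, captured through
  the endoscope by an 8-bit camera, and for each capture the pixels inside
  a circular region of interest (ROI) are binned by grey level. With $N$
  ROI pixels and the ascending cumulative histogram $F$, the contrast is
  $g_{75} - g_{25}$, where $g_q$ is the smallest grey level with
  $F(g_q) \ge \lceil q N / 100 \rceil$. The session's contrast is the
  arithmetic mean over the seven frequencies.

`endoqc` re-creates the whole bench in software: pattern generation, a
parameterised virtual endoscope that renders captures and photocell
readings, the two metrics, a measurement registry, database-relative
accept/reject rules, and longitudinal reports.

# Decision rules

All decisions are relative to the **best-of-type** baseline: the highest
stored value of the metric among all recorded endoscopes of the same
model, which defines the 100% reference level. The thresholds in
`qa_config()` are:

* **Acceptance** (new or repaired instruments): accepted when *both*
  transmission and contrast are at least **40%** of best-of-type,
  boundary inclusive.
* **Rejection** (clinically used instruments): rejected when *either*
  metric falls strictly below **20%** of best-of-type.
* **Significance**: a change between two measurements matters when its
  relative magnitude strictly exceeds **5%** — derived from the bench's
  own stability, since ~95% of reference-endoscope readings fall within
  2% (transmission) / 3% (contrast) of their means.

Three conventions here were genuinely open and are declared package design
choices, configurable through `qa_config()`:

* The two metrics are combined conservatively — AND for acceptance, OR
  for rejection — so a single bad pathway blocks an instrument.
* The acceptance boundary is inclusive ("at least 40%") while rejection
  is strict-below 20%; the rejection inequality direction was unstated.
* Significance is measured relative to the *previous* value, not a series
  mean.
* Moisture (a physical cold-spray observation, stored as a boolean) is
  flagged on every decision but never auto-rejects, mirroring observed
  clinical practice where leaking instruments stayed in use.

The quantile convention for contrast — smallest grey level reaching the
cumulative count, no interpolation — matches an integer-histogram
implementation exactly and is verified in the tests against a brute-force
sorted-pixel oracle.

# The virtual endoscope

`render_through_endoscope()` applies, in a fixed documented order:
circular field mask → Gaussian blur (`blur_sigma`, px) → veiling glare
$I' = (1-h)I + h\bar I$ inside the mask → radial vignetting
$1 - v(r/r_{max})^2$ → multiplicative dust discs → additive Gaussian
sensor noise (seeded) → clip and quantize to 8 bits. The glare transform
is applied inside the field mask only, so the region outside the image
circle stays black; nothing in the physical bench specifies this
pipeline, and the order is a reproducibility convention, not physics.
Ray-traced rod-lens optics, chromatic effects and real camera response
curves are deliberately out of scope.

Aging (`age_endoscope()`) uses the simplest model able to produce the
observed behaviours: per sterilization cycle, transmission decays
multiplicatively by $(1-r_T)$ while blur and glare grow additively. It is
compositional (`age(age(s,a),b) == age(s,a+b)`), and the closed form makes
test oracles trivial. Repairs restore mapped parameters toward factory
values by a seeded factor $f \sim U(0.9, 1)$: transmission to
$f \cdot \mathrm{factory}$, blur/glare/vignetting to
$\mathrm{factory} / f$ — so repaired instruments sit somewhat below
comparable new ones, as repair cohorts do in practice.

# The synthetic fleet: a stated world

`fleet_config()` fixes the world the tests run in; its defaults were
chosen once, from what the study design reports, and are not tuned to test
outcomes:

* **Sessions:** 20 sessions at 3.5-day intervals (measurements were taken
  twice a week), 5 sterilization cycles between sessions.
* **Reference endoscope:** never used clinically, zero degradation,
  measured once per session with 1% relative reading noise — so roughly
  95% of its transmission readings fall within 2% of the mean, matching
  the stability the bench demonstrated.
* **Clinical endoscopes:** 3 per type, factory transmission 0.75–0.95,
  slow per-cycle decay drawn from 0.001–0.004 — a few percent over the
  study window, the "slight downwards trend" regime.
* **One fast decayer per type** with per-cycle decay 0.016–0.024. Without
  it no instrument reaches the 20% rejection level inside a 20-session
  window and the world would contain no repair events at all; its rate is
  set so the rejection trigger fires late in the window. This is a
  modelling requirement of the stated world (rejection and repair events
  must exist), not a clinical estimate — no quantitative
  degradation-per-cycle data exists to calibrate against.
* **Repairs** (rod lens + fibres + dust clean) fire when ground-truth
  transmission falls below 20% of the type's best factory value; the
  repaired instrument is measured before and after in the same session.
* **Post-repair burn-in:** for 5 sessions after a repair the fibre decay
  rate is multiplied by 3, reproducing the rapid transmission drop seen
  after repairs (plausibly cleaning debris burning onto the fibre ends
  under a high-power source). Factor and duration are illustrative.

What a green test on this world establishes: the *pipeline* — rendering,
metrics, storage, decisions, trend statistics — behaves correctly and
deterministically on data with the study's qualitative structure. What it
does not establish: anything about real degradation rates, real repair
quality, or the clinical appropriateness of the 40/20/5 thresholds. The
simulator also omits moisture onset events (the moisture flag is
plumbed through records and decisions but the default fleet never sets
it) and any correlation between metrics beyond what the optics model
induces.

# Numerical and statistical choices

* **Drift/trend test:** ordinary least squares of the metric against days
  since first record, two-sided t-test on the slope at level 0.05. The
  bench's own criterion for "significant trend" was never specified; OLS
  is the simplest defensible stand-in and `trend()` reports slope,
  standard error and p-value so anything else can be computed downstream.
  Days (not session indices) are the time axis, since sessions are
  irregular. A series with zero residual variance reports its exact slope
  with no test (`p = NA`, not significant).
* **Line-pattern periods:** the seven spatial frequencies were never
  printed; periods follow
  $p_i = \mathrm{size} / (4 \cdot 2^{i/2})$, rounded to the nearest even
  integer (exact 50% duty cycle) and clamped at 2 px, spanning
  coarse-to-fine like a standard resolution chart. `default_pattern_suite()`
  refuses sizes where rounding collapses two adjacent frequencies
  (128 px is the smallest comfortable default sensor).
* **ROI detection:** threshold at the midpoint of the 10th/90th grey
  percentiles, largest 4-connected bright component, centroid +
  equivalent-area radius; components below 0.5% of the frame raise
  `endoqc_roi_not_found`. The ROI is located once per session from the
  circle capture and reused for all seven line captures (one mounting,
  one geometry).
* **Ties and boundaries:** contrast quantiles take the *smallest* grey
  level reaching the cumulative count; acceptance is inclusive; rejection
  and significance are strict. All three are exercised at the exact
  boundary in the acceptance tests.
* **Determinism:** every stochastic operation takes a seed; derived seeds
  are kept inside 32-bit signed range; `endoqc_demo()` with a fixed seed
  produces byte-identical CSV/JSON outputs.

# Known limitations

* The registry is an in-memory table with a CSV dialect
  (`serial,type_id,timestamp,transmission,contrast,moisture,context`,
  ISO-8601 UTC) rather than an SQL store; it is single-writer and
  desk-scale by design.
* Images are exchanged as ASCII PGM (P2) with JSON sidecars — universally
  readable and diff-able, but bulky for large sensors.
* Best-of-type updates continuously as records arrive; a frozen-baseline
  mode is a one-line variant (`best_of_type()` over a time-filtered
  registry) but is not the default.
* The blur/contrast relationship is monotone but not calibrated to any
  physical modulation-transfer function.
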