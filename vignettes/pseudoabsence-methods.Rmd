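---
title: "Pseudo-absence strategies for telemetry-based habitat models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-absence strategies for telemetry-based habitat models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoabs)
```

## The problem

Animal telemetry records where animals went, never where they did not go.
Fitting a binary habitat suitability model (a species distribution model) to
tracking data therefore requires *pseudo-absences*: simulated locations that
stand in for unvisited habitat. How those locations are generated is not a
nuisance detail — it determines what contrast the model is asked to explain,
and with it every skill statistic computed afterwards.

`pseudoabs` implements the four generation methods in standard use, the
movement statistics that parameterize them, three habitat-model families, and
the evaluation machinery needed to ask the uncomfortable question: *how much
of a model's apparent skill is just the environmental separation between
presences and wherever the pseudo-absences were put?*

## Pseudo-absence generation

All four methods produce exactly one pseudo-absence per presence (a 1:1
ratio, so class balance never differs between methods), every point lies
inside the study domain, and each record inherits the timestamp of its
matched presence so that dynamic covariates can be extracted without
temporal bias.

* **Background** (`background_sample`): points uniform *by area* over the
  domain. For a lon/lat bounding box the latitude is drawn with density
  proportional to cos(latitude); degree-uniform sampling would oversample
  high latitudes.
* **Buffer** (`buffer_sample`): one point uniform by area on the geodesic
  disc of radius *r* around each presence (bearing uniform, distance
  `r * sqrt(u)`). The radius convention is the mode of the empirical
  step-length distribution (`mode_step_length`). Points falling outside the
  domain are redrawn up to 20 times; a presence with no usable buffer area
  is skipped with a warning and replaced by a draw around another presence,
  preserving the 1:1 count. Buffers may overlap the presence itself — the
  method samples *within* a radius, with no exclusion zone.
* **CRW / reverse CRW** (`crw_simulate`): a correlated random walk that
  resamples *paired* (step length, turn angle) rows from the empirical
  movement distribution — pairs are never split, preserving the joint
  structure of speed and tortuosity. Forward walks start at the tagging
  location with the track's initial heading; reverse walks start at the last
  fix and assign timestamps backwards to the tagging date, countering
  tag-deployment bias. The start point is the walk's first record, which is
  what makes per-animal counts match fix counts exactly. A step landing
  outside the domain is redrawn up to 20 times, after which the heading is
  reflected (turned 180 degrees, a one-knob approximation to reflecting
  across the local boundary normal) and the turn angle alone redrawn.

Whole-track acceptance filters (selecting CRW tracks by net displacement or
mean travel angle) are deliberately not applied; they are an extension hook,
not part of the core procedure.

## Movement statistics

`regularize_track` resamples a track to exact multiples of the target
interval (defaults emulate daily ARGOS-style fixes or 6-hourly GPS collars),
interpolating positions linearly in time and never across gaps longer than
`max_gap_hours` — the track splits into segments instead, and never
extrapolates beyond its observed endpoints. Linear interpolation in lon/lat
is accurate at the km-to-100 km step scales the package targets; it is not a
great-circle interpolation, which would only matter for multi-thousand-km
gaps.

`empirical_moves` then emits one paired sample per interior fix: the
geodesic step length of the outgoing displacement and the signed bearing
change from incoming to outgoing displacement. Conventions, fixed and
tested: turn angles lie in (−π, π], counterclockwise positive (so a right
turn is negative); the incoming bearing is evaluated *at* the vertex (the
displacement's final bearing), which makes a straight geodesic yield exactly
zero turning; the first fix of a segment contributes no pair. Reversing a
track negates every turn angle.

The "mode step length" of a continuous sample is not well defined without a
rule, so the package uses a histogram mode: equal-width bins over
`[0, max step]`, default width 5% of the 95th percentile step (robust to a
long right tail), ties broken toward the smaller bin. Pooling across
individuals is the default; per-animal distributions are supported and are
used per-animal by the CRW generators when selected.

All geodesy is spherical (haversine distances, destination points from
bearing and distance) on the authalic radius 6371.0072 km — one convention,
accurate at both park (~10 km) and ocean-basin (~100 km) step scales.

## Habitat model families

`habitat_model()` fits one of three families to a presence/pseudo-absence
table, each binomial on the 0/1 label:

* **linear** — logistic regression with a linear term per covariate and a
  per-animal random intercept. The random intercept is a penalized
  (ridge-shrunken) group effect, `s(animal_id, bs = "re")` in `mgcv` — the
  standard equivalence between random effects and quadratically penalized
  coefficients.
* **smooth** — the same structure with a thin-plate spline per covariate,
  basis dimension 5 by default: enough for one hump or threshold, small
  enough not to chase noise in typical telemetry tables.
* **trees** — stochastic gradient-boosted trees (xgboost), learning rate
  0.005, bag fraction 0.75, interaction depth 5, 2000 trees — the
  long-standing slow-learning configuration for boosted ecological models.
  "Tree complexity 5" in the boosted-regression-tree literature is the
  per-tree interaction depth, and is mapped accordingly. No random effect:
  boosting has no natural shrunken-intercept analogue, and the bagged trees
  absorb individual heterogeneity nonparametrically.

Covariates enter untransformed. Predictions are population-level (the
random intercept is excluded at prediction time), so suitability maps do not
depend on which animal is asked for; they are always in [0, 1].
Explanatory power is the explained deviance
\((D_{null} - D_{resid}) / D_{null}\) on training data; for the trees family
both deviances are computed from training predictions against the
intercept-only fit. Values below 0 (possible out of sample, or for a
catastrophically bad fit) are clipped to 0 with a warning.

## Skill and separation metrics

* **AUC** is computed rank-based (Mann–Whitney), ties counted ½ — exactly
  the probability a random presence outscores a random absence.
* **TSS** is maximized over all midpoint thresholds between consecutive
  unique scores; the maximizing threshold is available on request. With a
  single unique score the only threshold predicts everything present,
  giving 0.
* **Bhattacharyya coefficient** between the presence and pseudo-absence
  samples of each covariate: \(\sum_i \sqrt{\hat p_i \hat q_i}\) over 50
  equal-width bins shared across the pooled range (50 bins resolves the
  distributions at the sample sizes the pipeline produces while keeping
  empty-bin noise modest; the count is configurable). 1 means identical
  binned distributions, 0 disjoint environmental niches.
* **Cross-validation schemes**: `full` (train = test, the scheme used for
  headline comparisons so all methods face identical information),
  `random75` (a single seeded 75/25 split), and `month`
  (leave-one-calendar-month-out, refused with an informative error when the
  data span fewer than two months — static-world studies cannot be held out
  temporally). Fold metrics are aggregated by unweighted mean.

The *separation–skill regression* (`separation_skill_regression`) is the
analysis the package exists for: OLS of AUC on the Bhattacharyya
coefficient, pooled within each model family over the four methods and the
top three covariates, with the two-sided p-value for the slope. "Top"
covariates are ranked by the boosted-trees relative influence (Gain) on the
full-data fits — "most important" has no single convention in the SDM
literature, so the choice is made explicit here and recorded in the report. p-values are reported unadjusted;
the analysis is a single pre-specified regression per family. A
significantly negative slope says that methods creating more environmental
separation *appear* more skillful, independent of any change in the
underlying biology.

## The synthetic world

Every downstream stage is testable without restricted telemetry or
remote-sensing downloads because the package generates its own ground truth:

* **Environments** (`generate_environment`): monotone gradient layers
  (direction and range configurable, emulating onshore–offshore physical
  gradients), Gaussian-smoothed white-noise layers standardized to zero mean
  and unit variance (emulating patchy biological fields; the smoothing
  length sets the autocorrelation range), and geodesic distance-to-feature
  layers (emulating distance to roads or water). Layers are static or
  monthly (12 slices; monthly gradients get a deterministic sinusoidal
  seasonal offset, additive so within-slice monotonicity is preserved). A
  configurable fraction of cells is masked missing. Grids are cell-center
  registered, row-major from the north-west corner, with containing-cell
  (no interpolation) extraction — which keeps extraction oracle-exact in
  tests and matches common SDM practice.
* **Tracks** (`simulate_track`): step-selection simulation. At each step,
  K = 10 candidate destinations are drawn from the movement kernel (paired
  Weibull step lengths, scale 15 km and shape 1.5 by default, and
  wrapped-normal turn angles, sd 0.6 rad — right-skewed steps and
  forward-concentrated turns, the canonical telemetry signature) and one is
  chosen with probability proportional to \(\exp(\sum_l \beta_l z_l)\),
  covariates standardized by domain-wide mean and SD so that β is in
  log-odds per SD and scale-free. This is the step-selection form, so the
  selection coefficients are a known, recoverable truth.
* **Studies** (`generate_study`): per-animal sub-seeds derived
  deterministically from one master seed (byte-identical reruns),
  uniform-by-area or clustered ("tag-deployment bias") start points.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: positional error (ARGOS class errors),
behavioural state switching, barriers and currents, observation gaps, and
real covariate fields' cross-correlations. The generator's role is to make
the *pipeline's* contracts and the separation–skill phenomenon testable,
not to simulate any particular species.

## Numerical and design choices

* Candidate selection retries: 20 rounds of redraws for out-of-domain
  candidates, then the least-missing in-domain candidate is accepted
  (missing covariate contributions score 0); with no in-domain candidate at
  all the heading is resampled uniformly (logged warning, at most 5 times)
  before the animal holds position for one step. Bounded work per step,
  no infinite loops on pathological domains.
* CRW boundary handling: 20 paired redraws, then heading reversal with 20
  turn-only redraws, then a hard error naming the step — silent degradation
  would bias the step-length marginal.
* Ties in the TSS threshold sweep and the histogram mode break
  deterministically (first maximum / smaller bin), so reruns are
  byte-stable.
* Missing-covariate rows are dropped (with a logged per-label count), not
  imputed — prediction maps show missing pixels for missing predictors, and
  the 1:1 balance is allowed to drift slightly after dropping (the drop log
  records by how much).
* All randomness in `run_all` flows from a single master seed through named
  sub-seeds per stage, so stages can be re-run in isolation and full reruns
  are byte-identical.
* Environments serialize to plain-text CSV plus a JSON geometry header;
  tracks, move distributions, tables and reports to CSV with ISO-8601 UTC
  timestamps.

## Scale of the shipped analyses

The package's own demonstration study (`default_config()`) uses a 60 × 60
grid of 0.1° cells with 5 animals × 120 daily steps, and the headline
separation–skill analysis is run at 10 animals × 200 steps with selection
coefficient 3 on the gradient layer — a deliberate reduced-scale analogue
of a multi-year, hundred-animal telemetry study, large enough for the
separation–skill relationship to be resolved yet small enough that the full
four-method × three-family experiment runs in minutes on a laptop. Property
tests that need many replicates (majority-over-seeds checks) use smaller
worlds still.

## Known limitations

* Linear time interpolation of positions (not great-circle) during
  regularization.
* Bounding-box and raster-mask domains only; no polygon geometry.
* Uniform-by-area sampling treats cells as spherical rectangles; fine at
  the sub-degree cell sizes used here.
* The trees family offers no per-animal random effect, so family
  comparisons conflate model flexibility with random-effect structure —
  exactly as in the modelling tradition the package mirrors.
* Monthly (not daily) temporal resolution for dynamic layers.
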