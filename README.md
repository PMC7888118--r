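# pseudoabs

Pseudo-absence generation strategies for telemetry-based habitat models —
and the machinery to measure how much of a model's apparent skill they
manufacture.

## The problem

Animal telemetry is presence-only: it says where tagged animals went, never
where they did not. To fit a binary habitat suitability model (species
distribution model) to tracks, one must simulate *pseudo-absences*, and
there are several conventions for doing it:

* **background** sampling — uniform by area over the whole study domain;
* **buffer** sampling — uniform on a geodesic disc around each presence,
  radius set from the mode of the empirical step-length distribution;
* **correlated random walks (CRW)** — resample the paired (step length,
  turn angle) distribution of the real tracks, walking forward from the
  tagging location;
* **reverse CRW** — the same walk backward in time from the last fix,
  countering tag-deployment bias.

The choice matters because it sets the environmental contrast the model is
asked to explain. `pseudoabs` implements all four methods (exact 1:1 ratio
with presences, domain containment, timestamps inherited from matched
presences for dynamic covariates), three habitat-model families — logistic
mixed models with linear terms (GLMM-style), with thin-plate spline smooths
(GAMM-style, basis dimension 5), and stochastic gradient-boosted trees
(learning rate 0.005, bag fraction 0.75, interaction depth 5, 2000 trees) —
and the evaluation suite: explained deviance
\((D_{null}-D_{resid})/D_{null}\), rank-based AUC (ties ½), True Skill
Statistic maximized over thresholds, three cross-validation schemes
(full-data, 75/25, leave-one-month-out), and the Bhattacharyya coefficient
\(\mathrm{BC} = \sum_i \sqrt{\hat p_i \hat q_i}\) between presence and
pseudo-absence covariate distributions over 50 shared bins.

The headline analysis regresses AUC on BC across methods and key
covariates, per model family. A significantly negative slope means skill
tracks environmental separation: methods that put absences in unfamiliar
environments *look* better regardless of the biology.

A synthetic-world module generates gridded environments (monotone
gradients, autocorrelated noise fields, distance-to-feature layers; static
or monthly) and habitat-biased tracks via step-selection simulation with
known selection coefficients, so the whole pipeline runs and is tested
end-to-end with no external data.

## Worked example

```r
library(pseudoabs)

spec <- env_spec(
  env_grid(-125, 45, 0.1, 60, 60),                 # 6 x 6 degrees, 0.1-deg cells
  list(layer_gradient("sst", direction_deg = 90, range = c(10, 25)),
       layer_noise("chl", correlation_length = 5),
       layer_noise("mld", correlation_length = 10)),
  seed = 7)

study <- generate_study(                            # known truth: prefers high sst
  spec, selection_params(c(sst = 3), move = move_param(25, 1.5, 0.6)),
  n_animals = 5, n_steps = 120, seed = 7, clustered_starts = TRUE)

moves <- empirical_moves(study$tracks)
mode_step_length(moves)
#> 6.2 km                                           # -> buffer radius

report <- evaluate_experiment(study, schemes = "full", seed = 7)
report
```

```
<skill_report: 4 method(s) x 3 family(ies) x 1 scheme(s)>
      method family scheme       r2   auc    tss mean_pred_presence ...
  background linear   full 9.14e-02 0.687 0.2694              0.559
  background  trees   full 4.19e-01 0.939 0.7124              0.693
      buffer linear   full 2.20e-06 0.502 0.0116              0.500
      buffer  trees   full 1.00e-01 0.758 0.3669              0.543
         crw  trees   full 4.59e-01 0.941 0.7306              0.716
 reverse_crw  trees   full 4.39e-01 0.934 0.7190              0.707
 ...

Separation (BC) vs skill (AUC) regression per family:
 family slope intercept p_value r_squared n_points
 linear -2.14      2.67 0.00105     0.675       12
 smooth -2.27      2.80 0.00106     0.674       12
  trees -2.11      2.89 0.00122     0.665       12
```

Reading it: buffer sampling keeps absences inside the animals' own
environmental niche (BC near 1), so every family scores near chance
(AUC ≈ 0.50) — there is almost no contrast to learn. Background and CRW
absences sample different environments, and AUC climbs accordingly. The
per-family regressions make that dependence explicit: AUC falls by ~0.21
for every 0.1 increase in environmental overlap, p ≈ 0.001, for *all three*
families. Skill here is a property of the sampling design, not the model.

Suitability maps (`predict_grid`) and per-covariate presence/absence
histograms round out the outputs; `run_all(default_config())` executes the
whole pipeline and writes every artifact (tracks, move distributions,
pseudo-absence sets, model tables, metrics, BC tables, regressions,
prediction grids) as CSV/JSON under one output directory, byte-identically
reproducible from its master seed. A thin command-line wrapper lives at
`inst/scripts/pa-pipeline.R`.

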