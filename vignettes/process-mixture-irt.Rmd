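---
title: "Modelling problem-solving process data with a multilevel mixture 2PL"
author: "mmixirt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling problem-solving process data with a multilevel mixture 2PL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmixirt)
```

## The measurement problem

In a route-selection problem-solving item, a student repeatedly toggles
routes on a map until satisfied with the selected path. The log file
records a full map state after every toggle. Each retained state is a
*step*, and each of the `I` routes plays the role of an item within the
step. The scoring convention makes 1 the "good" state everywhere: for a
route on the correct path the score equals its selection indicator; for a
route off the path it is the complement. The map is involutive — applying
it twice returns the selection — and a step scores all ones exactly when
the selection equals the correct path.

Steps are nested in students, and route-selection behaviour is
heterogeneous: different steps reflect different *strategies*. The model
therefore mixes latent classes at the process (step) level while keeping a
single continuous ability at the student level.

## Model

At the process level, step `j` of student `k` in class `g` follows a 2PL
per route on the logit-location scale,

$$P(\omega_{jki}=1 \mid \theta_{jkg}, C_{jk}=g)
  = \mathrm{logistic}(\alpha_{ig}\theta_{jkg} - \beta_{ig}),$$

routes conditionally independent given `(g, θ)`. The joint step
probability sums over classes with mixing proportions `γ_g` and integrates
`θ_jkg ~ N(μ_g, σ_g²)`. At the student level the *final* step follows a
2PL with `θ_k ~ N(0,1)`; its item parameters are tied to the reference
class so that the two ability scales coincide. The free-parameter count is
`2·I·G + 3(G−1)`.

Note the location parameterization: `β` is a logit offset, not the
classical difficulty `b = β/α`; `location_to_difficulty()` converts.

### Identification

The reference class (class 1 internally) has its ability distribution
fixed at N(0,1). For every other class, `(μ_g, σ_g)` trade off exactly
against `(α_{·g}, β_{·g})` along a likelihood ridge, because
`α(μ + σz) − β = (ασ)z − (β − αμ)`. With class-specific item parameters
the non-reference moments are therefore only weakly identified (the
discrete quadrature grid breaks the invariance marginally). The package
keeps the free-moments parameterization — it is the one that matches the
`2IG + 3(G−1)` accounting — but all parameter *comparisons* (recovery
experiments, label alignment) are done on the standardized within-class
scale via `standardize_params()`, where the ridge is quotiented out. An
alternative reading of the model constrains the overall process-ability
distribution rather than one class; we adopt the reference-class
convention because it is the one consistent with the parameter counts
above, and expose the counting variant for untied student-level item
parameters behind `tie_between_to_reference = FALSE`.

### Quadrature as a fixed discrete grid

The marginal likelihood is approximated on a fixed Gauss–Hermite grid
(default 15 nodes, `quadrature` argument; weights renormalized to sum to
one). Non-reference class distributions enter as renormalized
`N(μ_g, σ_g²)` density weights *on the same grid*. Two consequences:

- the objective maximized by EM is an exact function of the parameters
  (no moving grid), so the monotonicity of EM is a testable invariant, not
  an approximation; and
- accuracy degrades if `|μ_g|` is large or `σ_g ≫ 1`; the update for the
  moments is bounded (`|μ| ≤ 6`, `0.05 ≤ σ ≤ 10`) and, in practice, the
  ridge keeps fitted moments near their (0, 1) starting values.

Refinement checks in the test suite show 61-node agreement with dense
brute-force integration to below 1e-8 on small instances.

## Estimation

`mmixirt()` runs a multi-start generalized EM:

- **Starts** (default 20): locations initialized at scored-proportion
  logits plus class-specific Gaussian jitter (SD 0.7), discriminations at
  log-normal jitter around 1, mixing proportions at perturbed-uniform.
  Each start runs a 30-iteration burn-in (`short_iter`); the best is
  iterated to convergence. All randomness flows through `seed`, recorded
  in the result.
- **M-steps**: mixing proportions in closed form (floored at 1e-4 with a
  near-empty-class warning); per class and route, a damped Newton update
  of `(α, β)` accepted only on ascent of its expected complete-data
  log-likelihood piece; class moments by bounded quasi-Newton, likewise
  ascent-guarded. Because every update is guarded, the observed-data
  log-likelihood trace (`ll_trace`) is non-decreasing by construction and
  is asserted in the tests.
- **Convergence**: relative log-likelihood change below `tol = 1e-6` or
  `max_iter = 500` iterations; non-convergence is flagged, never silent.
- **Degeneracy**: parameters are capped at ±30 during optimization;
  estimates beyond ±15 in magnitude (far outside any plausible logit
  range, the signature of quasi-separation such as an all-ones response
  block) set the `boundary` flag and a warning.
- **Label switching**: after fitting, classes are relabelled by descending
  mixing proportion, ties by ascending class mean. Any permutation of
  labels leaves the likelihood invariant; the canonical order makes
  reports deterministic.

EAP abilities are posterior means on the quadrature grid: per step
(marginal over classes) and per student (final step under the tied 2PL).
Students sharing a final-step pattern necessarily share a student-level
EAP — which is why, in a group whose members all end on the identical
correct pattern, the student-ability column is constant and correlations
with it are undefined.

### Model selection

`select_classes()` tabulates `AIC`, `BIC`, `aBIC` and entropy across class
counts. The BIC/aBIC sample size is the number of level-1 steps `N1` by
default: the multilevel-modelling literature often argues for persons, but
the published comparison tables this package mirrors are arithmetic
consequences of the steps convention, so steps is the default and
`ic_n = "students"` the documented alternative. Entropy is
`1 − Σ(−p log p)/(N1 log G)`, in [0, 1], undefined at `G = 1`.

## Strategy characterization

- **Click attribution**: a step's toggles (Hamming distance to the
  student's previous state; a first step counts its set bits) belong to
  the step's modal class.
- **Signatures**: routes clicked above the class mean (or a top-k
  override) are ranked by clicks; retained routes sharing no endpoint with
  any other retained route are pruned. Endpoint-sharing is the only
  adjacency notion available from a route list, and it is weaker than
  visual map inspection: a route can share a node with a path while
  plainly branching away from it, in which case a human analyst would
  prune it and this rule would not. Tests therefore exercise pruning on
  maps where isolation is structural.
- **Episodes and shifts**: a run of three or more identical modal classes
  is an episode (three being the conventional stability threshold);
  episode labels in order form the shift sequence. A student with no
  qualifying run is "class 0" with 0 shifts; a single stable strategy
  counts 1. Same-label episodes separated only by sub-threshold noise
  collapse into one by default (`collapse_gaps`) — resuming a strategy is
  not a new shift — and the shift count is the number of episodes, not
  transitions, so that "no strategy" (0) and "one strategy" (1) remain
  distinguishable.

## Group comparisons

Selection proportions are percentages of a group's *steps* selecting a
route (the per-student denominator is available via `by = "students"`);
with dozens of steps per student, step proportions are the quantity that
varies smoothly. The χ² test is Pearson's without continuity correction,
the t test is pooled-variance (df `n1 + n2 − 2`), correlations are Pearson
with two-sided stars at 0.05/0.01/0.001, and no multiple-testing
correction is applied — these match standard reporting practice for this
kind of analysis. Constant columns (e.g. the student ability of a group
that uniformly ends on the correct pattern) yield `NA` cells rather than
spurious values.

## The synthetic-data generator

`simulate_mmixirt()` emulates the study conditions of a route-selection
log: 406 students by default, per-student step counts truncated-Poisson
with mean 39 on [1, 183], exponential inter-event gaps (mean 15 s, so a
39-step process spans roughly the observed ~11-minute median response
times), and an optional all-clear *reset* step rate. Per step it draws a
class from `γ`, an ability from the class distribution, and scored
indicators from the class 2PL; the final step is drawn from the
student-level 2PL with `θ_k ~ N(0,1)`, so the final pattern carries the
student-level signal. `emit_log()` serializes to the four-column log
dialect (apostrophe-prefixed 0/1 state strings, `start_item`/`end_item`
wrappers, optional redundant `hit_<route>` click rows), and the
emit–parse–rebuild round trip is bit-exact.

What the generator does *not* emulate: real consecutive map states differ
by exactly one toggle, while model draws are conditionally independent
given class and ability, so simulated click counts per step are larger
than real ones; reset steps are inserted, not behaviourally motivated; and
timestamps are memoryless. Passing tests therefore demonstrate
correctness of the machinery and recoverability of the generative model,
not behavioural realism of any particular dataset.

The bundled `traffic_task()` map carries invented per-route travel times
(the correct path constrained to sum to the 31-minute target), because
per-route minutes are not part of the published item material; they only
affect the `abs_time_diff` operational variable.

## Problem sizes and tolerances used in validation

Recovery experiments use 500 students × 30 mean steps for the
two-class design (item-parameter RMSE < 0.15, mixing proportions within
±0.03, assignment accuracy > 0.9 after alignment) and 300 × 20 for one
class; model-selection replication uses ten seeds of the same design.
Likelihood oracles run on 2–3 routes with dense trapezoid grids (400k
points, tolerance 1e-8); EM monotonicity is asserted on twenty seeded
runs. These sizes give stable Monte-Carlo behaviour at interactive run
times.

## Known limitations

- No standard errors or robust covariance for item parameters; inference
  about individual parameters should use the recovery machinery or
  resampling.
- Complete-step analysis only; malformed state rows are rejected with
  diagnostics, students with no retained step are excluded (and logged),
  and raw-versus-retained record counts can legitimately differ — both are
  visible from `parse_log()`'s rejected attribute and the dataset print.
- Response time is computed item-relative (last minus first event time of
  the item's events per student).
- The mixture is restricted to the process level; no student-level latent
  classes, no guessing parameter, and no covariates on class membership.
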