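# mmixirt

Multilevel mixture IRT modelling of problem-solving process data.

Computer-based problem-solving assessments (such as the PISA 2012 "Traffic"
route-selection item) record every action a student takes as a time-stamped
log event. `mmixirt` turns such logs into psychometric evidence: it recodes
the raw event stream into a step-by-route response matrix, fits a
**multilevel mixture two-parameter logistic (2PL) model** in which each step
belongs to a latent *strategy class*, selects the number of classes with
information criteria and entropy, scores ability at both the process level
(per step) and the student level (from the final step), and mines each
student's sequence of strategy classes for strategy *shifts*. A generative
simulator emits synthetic logs in the same dialect, so the whole pipeline is
testable without any confidential assessment data.

The package is aimed at psychometricians and learning analysts working with
action-level log files from computer-based assessments.

## The model

Let `ω_jki ∈ {0,1}` be the scored indicator of route `i` at step `j` of
student `k` (1 = "good state": a correct route selected, or a wrong route
not selected). At the process level, conditional on step class
`C_jk = g` and step ability `θ_jkg`,

    P(ω_jki = 1 | θ_jkg, C_jk = g) = exp(α_ig θ_jkg − β_ig) / (1 + exp(α_ig θ_jkg − β_ig))

with class-specific discriminations `α_ig` and locations `β_ig` (logit
scale). Routes are conditionally independent given class and ability; the
joint step probability mixes over classes with proportions `γ_g`
(`Σ_g γ_g = 1`) and integrates `θ_jkg ~ N(μ_g, σ_g²)` by Gauss–Hermite
quadrature, with the reference class fixed at N(0, 1) for identification.
At the student level, the final-step responses follow a plain 2PL,

    P(ω_ki = 1 | θ_k) = logistic(α_i θ_k − β_i),   θ_k ~ N(0, 1),

with item parameters tied to the reference class, so student-level
problem-solving ability `θ_k` is on the same scale as the process ability.
The free-parameter count is `2·I·G + 3·(G − 1)` (class-specific item
parameters, mixing logits, non-reference class means and variances); for
`I = 23` routes this gives 46, 95, 144, …, 389 parameters for `G = 1…8`.
Model selection uses `AIC = −2LL + 2p`, `BIC = −2LL + p·log(N1)`,
`aBIC = −2LL + p·log((N1+2)/24)` with `N1` the number of steps, plus the
normalized classification entropy.

Estimation is maximum marginal likelihood by a multi-start generalized EM
algorithm; every M-step update is ascent-guarded, so the log-likelihood
trace is non-decreasing by construction.

## Worked example

```r
library(mmixirt)

task  <- traffic_task()                         # 23-route demonstration map
truth <- example_params(task$n_routes, G = 2)   # well-separated 2-class bundle
sim   <- simulate_mmixirt(task, truth, n_students = 200, step_mean = 20,
                          seed = 42)

fit <- mmixirt(sim$data, classes = 2, starts = 5, seed = 42)
fit
#> Multilevel mixture 2PL fit: 2 class(es), 23 routes
#>   3954 steps from 200 students; logLik -47468.706 (95 free parameters)
#>   AIC 95127.413  BIC 95724.249  aBIC 95422.382  entropy 0.993
#>   class proportions: 0.631 0.369
```

The fit recovers the generating structure: two classes near the true 60/40
mix, and an entropy of 0.993 (posterior class memberships are essentially
crisp). Model selection over 1–3 classes picks the generating count by BIC:

```r
select_classes(sim$data, classes = 1:3, starts = 3, seed = 42)
#> Model selection over latent class counts (N1 = 3954 steps)
#>  classes n_params     loglik        AIC        BIC       aBIC    entropy
#>        1       46 -51853.206 103798.411 104087.405 103941.238         NA
#>        2       95 -47468.765  95127.529  95724.365  95422.498 0.99328017
#>        3      144 -47423.436  95134.872  96039.549  95581.982 0.83028238
```

Downstream analyses work from the fitted object: per-student ability and
operational variables, and strategy-shift mining over the modal class
sequence (runs of three or more identical classes form strategy episodes):

```r
log <- emit_log(sim$data, task)                 # PISA-dialect log table
ev  <- parse_log(log, task)
ov  <- operational_vars(ev, sim$data, task)     # clicks, resets, timing
stab <- student_table(fit, ov)                  # abilities + op. variables

tr <- strategy_traces(fit)
table(tr$n_shifts)
#>  0  1  2  3  4  5
#>  5 99 54 36  4  2
```

Here 99 of the 200 simulated students stick to a single stable strategy,
5 never settle into any strategy for three consecutive steps ("class 0"),
and the rest shift between strategies up to five times.
`correlation_table(stab[-1], group)` then reproduces the
ability-by-operational-variable correlation report, and
`class_signature()` extracts each class's characteristic route set (top
clicked routes, pruned of routes sharing no endpoint with the rest).

## Limitations

- Logs must be exported to delimited text first; SPSS binary files are not
  read directly.
- No standard errors for item parameters (no robust covariance estimation),
  and no missing-data handling beyond complete-step analysis.
- With class-specific item parameters, non-reference class means and
  variances are only weakly identified (a likelihood ridge); comparisons of
  parameter bundles should use the standardized scale
  (`standardize_params()`). See the methods vignette.
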