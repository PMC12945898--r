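---
title: "Dual evidence-accumulation modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual evidence-accumulation modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evaccum)
```

## The scientific problem

Two-choice response-time data are commonly summarized by the diffusion
decision model (DDM), whose drift rate `v` is often glossed as "processing
speed". Racing accumulator models decompose that notion into two distinct
quantities. In the linear ballistic accumulator (LBA), separate accumulators
for the response matching and mismatching the stimulus race to a threshold,
and two derived measures summarize their mean rates across task conditions:

* **EEA** (efficiency of evidence accumulation): the mean over conditions of
  `v_match − v_mismatch` — how selectively task-relevant evidence is
  accumulated;
* **SEA** (speed of evidence accumulation): the mean over conditions of
  `(v_match + v_mismatch) / 2` — how fast evidence accumulates regardless of
  its quality.

The two are an invertible linear transform of the average rates
(`v_match = SEA + EEA/2`, `v_mismatch = SEA − EEA/2`), EEA is invariant to
adding a constant to both rates while SEA shifts one-to-one, and in
simulation SEA moves mean RT while leaving accuracy nearly untouched whereas
EEA moves accuracy. `evaccum` implements the full pipeline needed to study
how the DDM's condition-averaged drift relates to these two quantities:
trial-level data handling and quality control, closed-form likelihoods for
both models with response-window censoring and a go-failure mixture,
individual Bayesian estimation by differential-evolution MCMC, posterior
predictive checking, and a mixed-model association stage — exercised end to
end on synthetic cohorts.

## The two likelihoods

**LBA.** Each accumulator starts at a point drawn uniformly on `[0, A]` and
rises linearly at a rate drawn once per trial from `Normal(v, sv)`; the
first to reach its threshold `b = A + B` wins. `sv_match` is fixed to 1 as
the scaling parameter. Rates are *untruncated* normals: a negative draw
means that accumulator never finishes, and a trial on which no accumulator
finishes is an omission. This choice (rather than truncating at zero) is the
canonical LBA form and makes the omission model coherent: the omission
probability is the mixture

```
P(omission) = p_gf + (1 − p_gf) · P(min finish time + t0 > window),
```

where the survival term includes the never-finish mass. Responded trials
contribute `(1 − p_gf) · f_win(rt − t0) · (1 − F_lose(rt − t0))`. The node
density and CDF use the standard two-Φ/two-φ closed form, with an
analytically simplified branch below `A < 1e−6` to avoid catastrophic
cancellation. In the n-back design the threshold gap `B` is shared across
responses and accumulator rates vary by trial type (target/lure/novel) and
match status; in the numerosity design thresholds are response-specific
(`B_many`, `B_few`) and rates vary over the four stimulus-by-difficulty
cells. A single `sv_mismatch` is shared across conditions; this is an explicit
modelling assumption of the package (per-condition rate SDs are a possible
extension but add weakly identified parameters).

**DDM.** A single accumulator starts at `z = z_rel · a` between boundaries 0
(mismatching response) and `a` (matching response) and drifts at a
condition-specific signed rate `v[c]` with within-trial noise fixed at
`s = 1`. Note the scaling convention: with the legacy `s = 0.1` convention
all rates and boundaries are ten times smaller, so comparisons with older
published estimates must rescale. The parameter set is exactly `v` by
condition plus `a`, `z_rel`, `Ter`, `st0`, `p_gf` — deliberately *not* the
"full DDM": no between-trial drift variability (`sv`) or start-point
variability (`sz`). The first-passage density is the infinite-series
solution, evaluated by whichever of the small-time or large-time
representation needs fewer terms at absolute tolerance `1e−10` (the two
agree to better than `1e−8` throughout their switching region). Nondecision
time is uniform on `[Ter − st0/2, Ter + st0/2]` and is integrated out by
11-point Gauss–Legendre quadrature (error below `1e−5` against a dense
trapezoid oracle on the tested grid; the order is configurable). Omissions
use the defective CDF, computed by term-wise integration of the large-time
series, through the same go-failure mixture as the LBA.

Both log-likelihoods have hot-path implementations in C++; the exported
single-trial density, CDF and omission functions are plain vectorized R, and
the test suite checks the C++ totals against brute-force composition of the
R functions trial by trial.

## Estimation

Each subject is fitted individually by differential-evolution MCMC:
`3 × n_params` chains; proposals `current + γ (chain_a − chain_b) +
U(−1e−3, 1e−3)` with `γ = 2.38 / sqrt(2d)`; ring migration with probability
0.05 per iteration during burn-in only. Convergence is gated on the maximum
univariate Gelman–Rubin statistic over parameters, computed on the second
halves of the retained chains, with threshold 1.10; sampling proceeds in
blocks until the threshold or an iteration cap is reached, and
non-convergence is reported as a flag, never an error.

Two standard stabilizers are on by default. Chains are initialized from the
best of a 10-fold oversample of prior draws — initialization does not affect
the stationary distribution, it only shortens burn-in. After burn-in,
chains whose log posterior lies far below the population (more than 2 IQR,
with a floor of 8 log units, under the median) are reset to the state of a
randomly chosen healthy chain and the population is briefly re-equilibrated
with migration; this is the usual guard against stuck outlier chains in
DE-type samplers. With these in place the practically relevant failure mode
that remains is slow mixing of the weakly identified LBA start-point range
`A` (and to a lesser degree `t0`), which at small iteration budgets leaves
R-hat between about 1.1 and 1.4 without materially affecting posterior
means; such fits are flagged `converged = FALSE` and are retained or dropped
per configuration.

Priors are broad, weakly informative, and user-overridable: rates
`N(1, 3)`; `N(1, 2)` truncated to positives for `a`, `A`, `B`,
`sv_mismatch` (sampled on the log scale); `t0`/`Ter ~ U(0.05, 1)` s;
`st0 ~ U(0, 0.5)` s; `p_gf ~ U(0, 0.2)` and `z_rel ~ U(0.1, 0.9)` sampled
through a probit transform (so the sampling-scale prior is standard normal).
They are deliberately broad defaults chosen to cover published DDM/LBA
parameter ranges rather than to encode prior findings. The start point is
estimated as relative (`z_rel`) for sampler geometry and reported both
ways.

## Derived measures and associations

EEA, SEA and the condition-averaged DDM drift `v_mean` are computed from
posterior means (medians by option). Because all three are linear in the
parameters, the point estimate of the derived quantity equals the derived
quantity of the point estimates. Posterior uncertainty is deliberately not
propagated into the association stage, which uses point estimates only.

The association stage fits random-intercept mixed models
(`criterion ~ EEA + SEA + (1|family) + (1|site)`, REML via `lme4`) and
reports each predictor's semipartial (part) R²: the marginal R² of the full
model — fixed-effects variance over fixed + random + residual variance —
minus that of the model with the predictor removed, floored at zero.
Confidence intervals come from a percentile bootstrap (1000 replicates by
default) that resamples top-level groups (families) to respect nesting;
row-level resampling is available by option. Grouping factors with fewer
than two levels are dropped, degenerating gracefully to OLS.

## The synthetic cohort generator

Because the motivating datasets sit behind access agreements, the package
generates complete synthetic studies. Subjects carry latent traits
`(EEA, SEA, B, t0, logit p_gf)` drawn from a multivariate normal — by
default mutually independent, with means/SDs in the range of published LBA
fits (EEA 1.5 ± 0.7, SEA 2.0 ± 0.6, B 1.0 ± 0.25, t0 0.30 ± 0.05 s,
p_gf centred on 0.02) — mapped to rates by the exact inverse of the EEA/SEA
definitions plus zero-sum condition offsets (lures harder, novels easier),
so the latent values *are* the condition-averaged derived measures and
parameter recovery closes the loop. Trials come from the exact LBA
simulator with window censoring and go failures; `A = 0.5` and
`sv_mismatch = 1` are constants of the population. Criterion scores are
`λ · standardized EEA + family intercept + site intercept + noise`, scaled
to unit variance, with default loading `λ = 0.45` (≈ 20% criterion
variance) and family/site intercept SDs 0.3/0.1 — SEA never enters, which
is what makes the association stage's expected pattern (EEA explains
variance, SEA does not) a ground truth rather than an empirical claim.

What the generator does *not* emulate: stimulus-level content (faces,
asterisk counts), sequential effects, practice or fatigue drifts, and
model-misspecification (data are generated by the LBA itself, optionally
the DDM). Passing tests therefore demonstrate internal consistency of the
pipeline — likelihoods, sampler, measures and inference — not that either
model is the true account of any empirical dataset. The DDM-fit stage on
LBA-generated data is a genuine cross-model fit, which is exactly the
situation of interest for the drift-versus-EEA/SEA question.

A note on what cross-model fits look like on these cohorts: regressing the
fitted DDM drift average on the latent traits shows it loads on both, with
the efficiency loading clearly larger (roughly 0.9 per unit EEA versus 0.6
per unit SEA on the default cohort) — faster accumulation at fixed
efficiency shortens and tightens RT distributions, which the DDM partly
absorbs into drift. The *correlation* gap between `v_mean`–EEA and
`v_mean`–SEA therefore sits near 0.3–0.4 in population terms and fluctuates
by ±0.1–0.2 across 40-subject cohorts; single-seed runs should be read with
that sampling noise in mind.

## Problem sizes and numerical choices

Routine runs and the reference study use 40 subjects × 3 conditions × 300
trials with fitting effort 400 burn-in + 400-iteration blocks capped at
800 post-burn iterations; at these sizes the true-versus-recovered
correlations computed by the acceptance script are about 0.97 for EEA and
0.90 for SEA, while a full pipeline run stays in the minutes range on one
core. A fuller cohort (`n_subjects = 200`) and higher caps are a
configuration change. Other fixed numerical choices: defective-density
integrals use adaptive quadrature at absolute tolerance `1e−6`–`1e−9`
(tests), series tolerance `1e−10`, Euler path simulation at `dt = 1e−3`
(simulation) or `1e−4` (oracle checks) with a 10 s time cap whose hits are
counted and recorded as omissions, and RT quantiles use linear
interpolation between order statistics (`stats::quantile` type 7) — fixed
and documented because no convention was stated in the source designs.

Open choices resolved here (each flagged in the relevant function's
documentation): QC accuracy is pooled across conditions with responded
trials as denominator; exactly-at-threshold subjects (accuracy = 0.55,
omission rate = 0.25) are retained, the rules being strict inequalities;
the MS-vs-seconds heuristic rejects rather than rescales; posterior means
rather than medians; family-level bootstrap rather than subject-level.

## Known limitations

* No hierarchical (group-level) estimation: subjects are fitted
  independently, matching the individual-estimation design this package
  reproduces.
* The LBA start-point range `A` mixes slowly at small iteration budgets;
  treat `converged = FALSE` fits' interval estimates for `A` and `t0` with
  caution (point estimates of rate-based measures are robust in the
  recovery checks).
* No model comparison machinery (Bayes factors, information criteria):
  model adequacy is assessed graphically/numerically through posterior
  predictive checks only.
* The Euler simulator's discretization slightly biases absorption
  probabilities (≈ 0.006 at `dt = 1e−4` for typical parameters); the
  analytic likelihood, not the simulator, is the reference implementation.

## A minimal worked run

```{r, eval = FALSE}
cfg <- study_config(seed = 1, n_subjects = 8, trials_per_condition = 100,
                    burn_in = 200, block = 200, max_iter = 400, n_boot = 200)
res <- run_study(cfg, out_dir = "study_out")
plot_recovery(res$measures)
plot_drift_relations(res$measures)
```
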