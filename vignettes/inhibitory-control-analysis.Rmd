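---
title: "Latent-variable analysis of inhibitory control batteries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable analysis of inhibitory control batteries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inhibitr)
```

## The measurement problem

Inhibitory control — the capacity to suppress a dominant response or ignore
distracting information — is usually measured with speeded conflict tasks.
No single task is a pure measure: observed scores mix the target inhibitory
process with task-specific skill and measurement error (the *task impurity
problem*), which is why correlations between inhibition tasks are
notoriously small. The standard remedy is a latent-variable design: give a
battery of tasks, score each one, and extract the shared variance with
confirmatory factor analysis (CFA). The structure of interest here is a
two-factor model: *prepotent response inhibition* indicated by the
antisaccade, Stroop and stop-signal tasks, and *resistance to distractor
interference* indicated by the flanker, shape-matching and word-naming
tasks, with a free correlation between the factors.

`inhibitr` implements this full chain — simulation, trimming, scoring,
reliability, and covariance-structure modelling — as tested, reusable
code. Because the interesting failure modes live in the interaction of
scoring rules, trimming and model fitting, the package ships a trial-level
generator with known ground truth so every downstream stage can be tested
by parameter recovery rather than by eyeballing.

## The synthetic battery

`generate_battery()` simulates six tasks with the conventional trial
counts: antisaccade 90 trials; Stroop 240 (80 congruent / 80 incongruent /
80 neutral); stop-signal 440 (330 go, 110 stop = 25%, stop-signal delays
on a 0–500 ms grid in 100 ms steps, split evenly with the remainder placed
at random); flanker 160 (40 per condition); shape-matching and word-naming
168 each (one third no-distractor).

The generating model, per subject *i* and task *t*:

* **Latent structure.** Factor scores (RI, DI) are standard bivariate
  normal with correlation `rho` (default .67). The true interference
  effect is `delta_it = mean_t + sd_t (lambda_t F_i + sqrt(1 -
  lambda_t^2) u_it)` with `u_it` independent standard normal — so
  `lambda_t` is exactly the population standardized loading of the true
  effect on its factor.
* **Reaction times** are ex-Gaussian, `N(mu_t + speed_i + w_c delta_it,
  sigma_t) + Exp(tau_t)`, where `w_c` is the condition's effect weight
  (1 for the interference condition, 0 for control, intermediate for the
  flanker's same/compatible noise conditions). The ex-Gaussian gives the
  right-skewed RT distributions real batteries show. `speed_i ~ N(0,
  speed_trait_sd)` is a general speed trait shared by all of a subject's
  tasks.
* **Errors** are Bernoulli with a logistic model: a task intercept, a
  bump in interference conditions, a term linking a subject's true effect
  to interference-condition errors, and `- slope * speed_i / sd(speed)`.
  The negative sign couples *fast* subjects to *higher* error rates,
  reproducing the negative subject-level RT–error correlations seen in
  real data (a speed–accuracy trade-off). A small fraction of fast-guess
  trials (uniform 80–350 ms, chance accuracy) exercises the anticipation
  trimming rule.
* **Antisaccade** is error-based: its latent effect *is* the target error
  proportion (clamped to [.005, .95]), moved on the logit scale by the
  speed trait, plus a smaller RT slowing (`antisaccade_rt_scale * delta`)
  so the inverse-efficiency scheme also carries signal.
* **Stopping** is an independent horse race: each stop trial samples a
  latent go finishing time; the subject responds iff it beats
  `SSD + true_ssrt`, with `true_ssrt` a subject constant (mean 322 ms,
  SD 40 ms, floored at 50 ms).

Defaults were calibrated once so group-level summaries land in the
realistic range for this battery (Stroop effect near 50 ms, antisaccade
error rate near .16, shape effect near 160 ms, mean SSRT near 322 ms);
they are a fixture of the generator, not a fitted quantity. A single
global seed is expanded into per-(subject, task) substreams, so generated
data do not depend on iteration order.

What the generator deliberately does *not* emulate: eye movements and
direction-error misdetection in the antisaccade task, voice-key artifacts
in word naming, sequential effects (post-error slowing, condition-order
effects), RT autocorrelation, and staircase SSD tracking (the battery
modelled here uses fixed random SSDs). Passing recovery tests on this
generator therefore shows the *pipeline* is correct under a realistic
noise model — not that any particular empirical dataset satisfies that
model.

## Trimming protocol

`trim_rt_pool()` applies, in fixed order: (1) drop error trials, trials
without a response, and RTs under 200 ms from the RT pool (error rates
are always computed on the full table); (2) winsorize to fixed per-task
bounds — Stroop (400, 2000), word-naming (200, 1000), flanker (200,
1500), others (200, 2000) ms; (3) within each subject × task × condition
cell, replace values beyond 3 SD of the cell mean with the boundary,
moments computed once on the untouched cell (single pass; the stop-signal
task is exempt because SSRT is quantile-based and extreme go RTs do not
drive it). After scoring, (4) each outcome column is winsorized across
subjects with the same 3 SD rule. Cells with fewer than two values or
zero SD are left alone. One subtlety worth knowing: a single winsorizing
pass shrinks the moments, so values clamped exactly onto the old boundary
can sit outside a *recomputed* 3 SD band — the guarantee is containment
in the band used for clamping, not idempotence.

## Scoring

Two schemes, both oriented so lower = better:

* **RT scheme**: Stroop incongruent − congruent, flanker
  noise-incompatible − no-noise, shape/word distractor − no-distractor
  mean correct RT differences (ms); antisaccade error proportion; and the
  race-model SSRT for the stop-signal task.
* **IES scheme**: the same contrasts on inverse efficiency scores,
  `IES = RT / (1 - ER)` per condition (ms; undefined at ER = 1, flagged
  missing); antisaccade uses its single-condition IES. The stop-signal
  column is the SSRT under both schemes, since SSRT already integrates
  speed and accuracy. With all error rates zero the two schemes coincide
  exactly — a useful invariant that the test suite checks.

**SSRT** uses the constant-SSRT race-model estimator: for each delay d,
estimate p_d = P(respond | SSD = d) from that delay's stop trials only;
rank-order all go RTs; the delay's estimate is `RT_(n) - d` with
`n = N_go * p_d`; average over delays with `0 < p_d < 1`. Non-integer
ranks interpolate linearly between adjacent order statistics (a
`rank_mode` flag restores integer-rank conventions); ranks clamp to
`[1, N_go]`. Delays at p = 0 or 1 are excluded because the relevant
order statistic is undefined or degenerate; a subject with no eligible
delay gets an explicit missing value, never a silent zero.

## Psychometrics

Split-half reliability splits odd/even trial indices within each subject
× condition cell (deterministic and condition-balanced; the conventional
default where no scheme is specified), scores each half with the full
pipeline, correlates the halves and applies the Spearman–Brown step-up
`2r / (1 + r)`. Between-task associations use Spearman rank correlations
(average ranks for ties; two-sided p from the t approximation),
unadjusted for multiple testing. Bivariate influence diagnostics report
leverage, externally studentized residuals and Cook's D from the simple
regression, flagging leverage > .05, |residual| > 3, or a top Cook's D
more than 3× the runner-up ("much larger than the rest" made
operational), and report the correlation with and without flagged cases.

## The CFA engine

Four models over the six outcomes: the null (independence) model, one
factor, two unrelated factors, two related factors; 15 / 9 / 9 / 8 df
against the 21 unique second-order moments. Identification fixes factor
variances at 1 (so the inter-factor correlation and fully standardized
loadings are directly interpretable). Estimation minimizes the ML
discrepancy

    F = log|Sigma(theta)| - log|S| + tr(S Sigma(theta)^-1) - p

with BFGS on an unconstrained parameterization (log error variances,
tanh-scaled correlation), at least five deterministic jittered starts,
and a polish pass; `chi^2 = (N - 1) F`. Because F is invariant under
diagonal rescaling, optimization runs in the correlation metric and maps
back — this makes convergence scale-free when outcomes mix proportions
(antisaccade) with millisecond scores. Error variances stay positive by
construction; solutions pressed against the zero bound (or standardized
loadings above 1) raise Heywood flags rather than being clipped
silently. Sign indeterminacy is resolved by making each factor's loading
sum nonnegative.

Fit indices follow the conventional definitions: `RMSEA =
sqrt(max(chi2 - df, 0) / (df (N - 1)))`; SRMR as the root mean squared
correlation-metric residual over the 21 unique cells; CFI and NFI
against the null baseline; `AIC = chi2 + 2q`. The AIC parameter count
`q` includes the six indicator means in addition to the
covariance-structure parameters — the convention used by the SEM
software this table format comes from (an `include_means` flag switches
to the covariance-only count). Model comparison ranks by AIC and
annotates the usual verbal thresholds (RMSEA < .01/.05/.08, SRMR
< .05/.08, CFI/NFI > .95).

Stability is assessed by nonparametric bootstrap: resample subjects with
replacement (5000 by default), refit warm-started from the full-sample
solution, align factor signs, and report bootstrap SEs and bias-corrected
percentile p-values (BC, not BCa — acceleration is not estimated).
Multivariate normality is checked with Mardia's skewness and kurtosis
(computed via a whitened data matrix rather than the n × n Gram matrix,
so large samples are cheap) and per-subject Mahalanobis distances flagged
against chi-square(6) at alpha = .001.

## Numerical and design choices

* Correlation-metric optimization with analytic back-scaling (see above);
  gradient-norm convergence check on the scale-free objective.
* The null model's optimum has the closed form `theta = diag(S)`, giving
  `chi2 = -(N - 1) log|R|`; the optimizer is verified against this closed
  form in the tests rather than replaced by it.
* Bootstrap refits that fail to converge are counted and excluded, never
  silently imputed.
* Trimming moments are computed once per cell (single pass), matching a
  protocol described as one replacement step.
* The ingest path validates trial files row by row (task and condition
  labels, SSD grid, stop-trial fields) and reports offending row numbers.

## Problem sizes in the test suite

The package's property tests use sizes chosen to make Monte-Carlo error
negligible relative to the tolerance being asserted: latent-moment
recovery at 50 000 subjects (tolerance .02), SSRT consistency over 200
simulated sessions of 330 go / 110 stop trials (±15 ms), end-to-end
recovery on twenty 1000-subject batteries, reliability recovery at 500
subjects, and a 500-resample bootstrap against observed-information SEs
at n = 2000. The recovery suite runs under a *low-trial-noise* regime
(trial-level RT noise scaled to 0.2×, 0.4× for the stop task so at least
two SSDs keep non-degenerate response probabilities; between-subject
SSRT SD raised to 60 ms against ~10 ms estimation noise; antisaccade
effect mean .22 / SD .13, clear of the probability floor). The point of
that regime: a CFA loading estimated from observed scores is attenuated
by the square root of the score's reliability, and the antisaccade task's
90 Bernoulli trials put a hard ceiling on attainable reliability — the
regime keeps every task's true-score variance fraction near or above .9
so the recovery band (±.10 around the generating values) reflects the
estimator, not the noise floor.

## Limitations

The generator's error model is Bernoulli-logistic with no lapse mixture;
its speed–accuracy coupling is subject-level, not within-trial. The SSRT
estimator is the constant-SSRT mean method — integration-style estimators
with RT-distribution modelling are out of scope, as are Satorra–Bentler
robust corrections, FIML for missing data, and mean-structure modelling.
IES is known to amplify variance when error rates exceed ~10%; the
package computes it as defined and leaves the interpretive caveat to the
analyst. Subjects with no eligible SSD are dropped listwise from the
covariance matrix, which slightly reduces the effective N at extreme
parameter settings.
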