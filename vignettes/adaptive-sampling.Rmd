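---
title: "Adaptive subsampling learning curves: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive subsampling learning curves: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(adaptsize)
```

## The estimation problem

Given a data pool $D$ of $N$ samples, we want to know how a model's accuracy
changes as the dataset grows, and from that, how much data would be needed to
reach a target accuracy or a target uncertainty. Measurement is simulated by
subsampling: drawing $d_n = \mathrm{round}(nN/100)$ rows without replacement
mimics collecting a dataset of that size from the population the pool
represents. By the law of large numbers the accuracy computed on such
samples converges to its population value as $d_n$ grows; what the pool can
tell us — and what no theorem supplies — is the *speed* of that convergence.

Two assumptions are load-bearing. First, *no data drift*: the pool must be
representative of future data, otherwise the extrapolated limit is the limit
of the wrong population. Second, *monotone convergence*: the power-law
summary (below) describes saturating curves; genuinely non-monotone
convergence calls for inspecting the stabilized distributions directly
rather than trusting any three-parameter fit.

## Stabilization: the adaptive repetition loop

A single subsample of size $d_n$ yields one accuracy value; its run-to-run
variation is exactly what makes naive learning curves irreproducible. The
package therefore estimates, at each ladder size $n$, the full *distribution*
of accuracies over repeated draws — and decides adaptively how many draws
that takes:

1. $m \ge 2$ parallel **instances** each accumulate repetitions in blocks of
   $k_0$: draw $d_n$ rows, split them $c:(1-c)$ into train and test,
   standardize features by the training split's mean and (population)
   standard deviation, fit the adapter, record train and test $R^2$.
2. After each block, the four **characteristics** — mean, median, 25th and
   75th percentile — of every instance's distribution are compared pairwise,
   separately for the train and test splits.
3. If every pairwise difference is within tolerance, the size is
   **stabilized** and the loop breaks; otherwise each instance receives
   another $k_0$ repetitions (previous values are never discarded).

The stopping rule uses a plain tolerance rather than a hypothesis test: the
comparison is re-run an unknown number of times as $k_n$ grows, so any
fixed-level test would face an unbounded multiplicity problem, and a
tolerance expresses what the user actually cares about — "the summaries I
will fit curves to should not move by more than this between runs".

Two instances sampling the same pool are two draws of the same random
process, so requiring all characteristics to agree within tolerance bounds
the run-to-run variability of everything computed downstream.

### Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `split_fraction` ($c$) | train share of each subsample | 0.7 | common hold-out convention |
| `ladder` ($S$) | pool percentages studied | 10, 20, …, 100 | ten sizes spanning the pool; smallest entry keeps the test split ≥ 10 samples on mid-sized pools |
| `instances` ($m$) | parallel distributions compared | 2 | minimum that permits a pairwise comparison; larger $m$ buys confidence at proportional cost |
| `base_reps` ($k_0$) | block size | 300 | large enough that quartiles of a block are meaningful, small enough not to overshoot |
| `tolerance` | max pairwise characteristic difference | 0.001 | on an $R^2$ scale: stabilizes the third decimal |
| `max_reps` | safety cap per instance | $100 k_0$ | the loop has no termination guarantee for pathological tolerances; capped sizes are flagged `converged = FALSE`, never silently accepted |
| `n0_init` | "not found" sentinel for $n_0$ | 101 | larger than any ladder percentage |
| `sig_level` | baseline test level | 0.05 | customary default; configurable |

The tolerance applies to all four characteristics; a named vector
(`mean`, `median`, `q25`, `q75`) sets them individually.

### Numerical and procedural choices

* **Rounding of $d_n$**: half-up, floored at 2 (a subsample must be
  splittable).
* **Tolerance comparison is inclusive** (≤): a difference exactly at
  tolerance passes, avoiding knife-edge non-termination; at float precision
  the distinction is immaterial.
* **Percentiles** use linear interpolation between order statistics
  (`quantile` type 7, the R and NumPy default).
* **Increment rule**: $k_n \leftarrow k_n + k_0$ per failed round. Constant
  increments waste nothing when the required $k_n$ is large, unlike
  multiplicative growth which overshoots.
* **Seeding**: the master seed spawns one deterministic stream per (size,
  instance, block) via integer mixing. Results are therefore bit-reproducible,
  independent of execution order, and *append-only*: tightening the tolerance
  extends the same value sequences instead of resampling them. A consequence
  used by the tests: effort ($k_n$) is monotone in tolerance on a fixed
  stream.
* **Standardization** is fit on the training split only and applied to both
  splits, so no test information leaks into scaling.
* **$R^2$** is computed against each split's own mean. An adapter may
  substitute any scalar score via its `score` function.
* **Performance**: the repetition count at tight tolerances reaches $10^5$ to
  $10^6$, so the bundled OLS and KNN adapters carry compiled evaluation
  kernels (indices are still drawn from the R streams; a test asserts the
  compiled and interpreted paths agree numerically), and the per-round
  convergence check maintains incrementally merged sorted arrays instead of
  re-sorting.

## The shuffled-target baseline and $n_0$

At small sizes a model may fail to learn anything that generalizes. The
baseline quantifies this: the same stabilization machinery is run with the
training targets randomly permuted before each fit (features untouched, the
target's marginal distribution preserved exactly), giving a no-signal
reference distribution $b$ alongside the real one $a$. Scanning the ladder
upward, $n_0$ is the first size at which, for *every* instance, a one-sided
Mann–Whitney U test finds the real test accuracies stochastically larger
than the shuffled ones ($p <$ `sig_level`) *and* the real mean test accuracy
exceeds the shuffled one. If no size qualifies, $n_0$ keeps its sentinel
(> 100): the target may simply not be predictable from these features.

The exact U distribution is used for small tie-free samples and the normal
approximation with tie correction otherwise (`stats::wilcox.test`; the exact
one-sided p-value is $P(U \ge u_{\mathrm{obs}})$, which the test suite
verifies against brute-force enumeration of all rank assignments).

Curve fitting can optionally exclude pre-learning sizes. We exclude sizes
**below** $n_0$ — the region where learning has not started — because those
points describe a different regime than the one being extrapolated. (The
opposite rule, dropping sizes at and above $n_0$, is selectable via
`n0_rule = "at_and_above"` for comparison, but it discards precisely the
informative points and is not the default.)

## Power-law summary and extrapolation

For each split, characteristic and instance, the stabilized values define
points $(c\,d_n, y_n)$ (train) or $((1\!-\!c)\,d_n, y_n)$ (test), to which
$f(d) = \alpha d^\beta + \gamma$ is fitted by unweighted least squares — all
points were stabilized to the same tolerance, so equal weights are the
honest choice. Fitting uses Levenberg–Marquardt from multiple starts:
$\gamma_0$ = last observed value, $\alpha_0$ = first − last,
$\beta_0 \in \{-0.25, -0.5, -1\}$; the lowest residual sum of squares wins,
and the round-trip tests require recovery of noiseless curves to $10^{-6}$.
$\beta$'s sign is unconstrained (training curves can fall toward the limit
while test curves rise). Constant inputs yield a degenerate fit with
$\gamma$ equal to the constant and $\beta$ flagged unidentifiable; optimizer
failure is reported as `converged = FALSE`, never a silent bad fit.

$\gamma$ is the limit accuracy; `required_sample_size()` inverts the curve
and returns `"unreachable"` for targets at or beyond the asymptote;
`uncertainty_width()` evaluates the fitted interquartile band; and
`percentile_crossing_check()` brackets and bisects the first point where the
25th-percentile curve meets the 75th — beyond a crossing the fitted curves
are outside their region of validity and extrapolations should not be
trusted. Hold-out validation of the curve family itself is available by
fitting only the first $q$ ladder points (`first_points = q`) and judging
the prediction on the rest.

Fits are per instance and characteristic; aggregation (mean ± sd of
$\gamma$ across instances and runs, `limit_accuracy_table()`) is a reporting
step, deliberately separate from fitting.

## Statistic mode

When the quantity of interest is a test statistic rather than a model score
(e.g. the mean of a biomarker under treatment), each repetition draws $d_n$
rows and partitions them into $m$ equally large sub-samples of
$\lfloor d_n/m \rfloor$ rows — the randomized draw order makes the dropped
remainder rows uniform — and the statistic of sub-sample $j$ extends
instance $j$'s distribution. There is no train/test split; everything else
(blocks, characteristics, tolerance, cap, seeding) is the same shared code
path. Disjoint sub-samples were chosen over resampling with replacement
because partitioning a single draw is the direct analogue of splitting a
measured dataset. `effect_difference()` then contrasts two stabilized
studies (same ladder and configuration) size by size — the effect-strength
input for a power analysis; computing power itself is out of scope.

## The synthetic generator as ground truth

`generate_pool()` draws i.i.d. standard-normal features and sets
$y = Xw + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$. Its purpose is
*calibration*: under this design the best achievable test $R^2$ is known in
closed form, $L = \sum w_i^2 / (\sum w_i^2 + \sigma^2)$, so the fitted
test-curve asymptote has an analytic target — the package's parameter-recovery
tests use weight 1 and $\sigma = 1$, i.e. $L = 0.5$ exactly. What the
generator does *not* emulate: correlated or non-Gaussian features,
heteroscedastic or heavy-tailed noise, nonlinear signal, discretized values
with distance ties. Passing the synthetic tests therefore demonstrates
correct mechanics and calibration of the pipeline, not robustness to those
real-data features.

Sub-sample means drawn without replacement from a fixed pool carry the
finite-population correction $\sqrt{(N-s)/(N-1)}$; the statistic-mode tests
check the CLT $1/\sqrt{s}$ rate against that exact oracle.

## Reference adapters

* `ols_adapter()` — linear regression with intercept; rank-deficient
  training sets (possible when a subsample's training side has fewer rows
  than features) fall back to the minimum-norm least-squares solution, so
  the heavily overparameterized regime (train $R^2 = 1$, strongly negative
  test $R^2$) is represented rather than erroring.
* `knn_adapter(k)` — uniform-weight KNN regression using *exactly* $k$
  neighbors (ties at the $k$-th distance broken by row index). The
  convention matters on discretized data, where averaging over all tied
  neighbors gives a visibly different estimator. The effective $k$ is capped
  at the training-set size; note that a capped size no longer evaluates the
  same model as the uncapped sizes, so learning-curve studies of a
  $k$-neighbor model should use a ladder whose smallest training set holds
  at least $k$ rows (e.g. start the ladder at 20% rather than 10% when
  comparing $k = 50$ on a few-hundred-row pool).

## Problem sizes used by the test suite

The suite stabilizes synthetic pools of 500–2000 rows and the standard
442-row diabetes benchmark (exported from scikit-learn at test time) at
tolerances between 0.025 and 0.001 with $m = 2$ and $k_0 = 300$; at
tolerance 0.001 the smallest ladder sizes receive $10^5$–$10^6$ repetitions,
which is why the replication recipes raise `max_reps` to $10^6$ — the
algorithm itself has no cap, and the default $100 k_0$ is a safety valve for
interactive use. Benchmark-replication runs take a few minutes each on one
CPU with the compiled kernels.

## Known limitations

* The power law is a summary, not a law; hold-out curve validation and the
  quartile-crossing check are the built-in guards, and disagreement between
  them and the fit is a signal to collect more data before extrapolating.
* Limit accuracies fitted from test-set abscissas are sensitive to the
  smallest ladder sizes, where test splits are tiny and the $R^2$
  distribution has a heavy negative tail; the fitted transient can then
  saturate too early. Ladders whose smallest test split is very small (≲ 15
  samples) shift the fitted test asymptote by ~0.01 on benchmark-sized
  pools. Choose the ladder's lower end with the test split, not just the
  training split, in mind.
* Time-series data violate the exchangeable-split assumption and are out of
  scope.
* Hyperparameter tuning inside the repetition loop is out of scope: a study
  characterizes one fixed model configuration; comparing configurations
  means running the study per configuration (as the KNN neighbor-count
  comparison does).
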