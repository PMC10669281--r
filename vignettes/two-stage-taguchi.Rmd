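---
title: "Two-stage Taguchi optimization: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage Taguchi optimization: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsto)
```

## The problem

Tuning the hyperparameters of a predictive model by grid search is
exponential in the number of hyperparameters: six factors at three levels
with three training replicates already cost $3^6 \times 3 = 2187$ model
fits. Robust parameter design offers a drastically cheaper alternative:
evaluate the model only at the runs of an orthogonal array, estimate each
factor's *main effect* from the array's built-in balance, and predict the
response at the recommended setting under an additive model. `tsto`
implements this as a two-stage procedure for black-box objectives such as
"train a neural network, measure test accuracy": a coarse screening stage
over all factors, followed by a refinement stage that re-levels the
surviving numeric factors around the stage-1 winner with halved spacing.

## Orthogonal arrays

An array $L_a(b^c)$ has $a$ runs and $c$ columns of $b$ levels, balanced
so that within each column every level appears equally often and, for
every pair of columns, every ordered level pair appears equally often.
This pairwise balance is what lets level means estimate main effects
without bias from the other factors. The catalog stores the classical
arrays L4, L8, L9, L12 and the mixed-level L18($2^1\times3^7$) as literal
integer matrices rather than generating them algorithmically: the
canonical L18 row order matters (the bundled worked example assigns its
six factors to columns 2–7 of exactly this variant), and a fixture test
pins it. `oa_verify()` re-checks both balance properties exhaustively;
factors with fewer levels than their column are rejected rather than
dummy-leveled, since dummy treatment changes the DF bookkeeping below.
Columns left unassigned are kept in the plan: their variation ends up in
the ANOVA residual.

## Signal-to-noise ratios

Replicates of a run capture noise — here, the retraining randomness of a
classifier. Each run is summarized by its replicate mean, sample SD
(denominator $n-1$), and a decibel-scale SN ratio. For a
larger-the-better response (accuracy),

$$\mathrm{SN}_{LTB} = -10\log_{10}\Bigl(\frac{1}{n}\sum_i 1/y_i^2\Bigr),$$

with smaller-the-better ($-10\log_{10}(\overline{y^2})$) and
nominal-the-better ($-10\log_{10}(\overline{(y-m)^2})$) variants for other
orientations. Base-10 logarithms are used throughout (the decibel
convention). The nominal-the-better identity
$\overline{(y-m)^2} = (\bar y - m)^2 + S^2$ holds with the *population*
variance (denominator $n$); the summation form is implemented as primary
and the identity is covered by a test with population variance. An ideal
response (zero mean square) yields `Inf` rather than an error. The grand
SD reported alongside the grand mean is the mean of the per-run sample
SDs — this is what a summary row of such tables conventionally holds, and
it reproduces both bundled summary rows.

## Response tables, pooled ANOVA

ANOVA operates on **per-run summary responses** (the per-run mean, or the
per-run SN), never on raw replicates: a design of $a$ runs has $a-1$
total DF (17 for L18, 8 for L9). For factor $f$ with $L$ levels,
$SS_f = (a/L)\sum_\ell (\bar y_\ell - \bar y)^2$ with $L-1$ DF. Minor
factors are *pooled*: their SS joins the error term together with the
residual from unassigned columns, $SSE = SST - \sum_{\text{unpooled}} SS$,
giving the error variance $V_e = SSE/\nu_2$ needed for F tests and
confirmation intervals. In the worked example's screening stage, pooling
four of six factors gives $\nu_2 = 17 - 4 = 13$ (8 pooled-factor DF plus
5 residual DF).

The default pooling rule retains the $k$ largest-SS factors ($k = 2$) and
pools the rest; an explicit pooled set can be passed instead. Factor
screening uses $p < \alpha$ with $\alpha = 0.1$; confirmation intervals
use $\alpha = 0.05$. Decisions always use unrounded p-values; report
files round for display only (4 decimals on the accuracy scale, 3 on SN
and p). Effect ranks break ties by factor declaration order, and best
levels are chosen by the mean response, then the SN response, then the
lower level index (the cheaper setting).

## Additive prediction and confirmation

The predicted response at a chosen setting is

$$\hat y = \bar{\bar y} + \sum_{f \in \mathcal F}(\bar y_{f,\ell^*} - \bar{\bar y}),$$

summing only over the retained (unpooled) factors $\mathcal F$ — pooled
factors' deviations are noise by assumption. The prediction is validated
by $r$ fresh confirmation runs against the half-width

$$CI = \sqrt{F(\alpha; 1, \nu_2)\; V_e \left(\tfrac{1}{n_{\mathrm{eff}}} + \tfrac{1}{r}\right)},
\qquad n_{\mathrm{eff}} = \frac{a}{1 + \sum_{f \in \mathcal F} \nu_f}.$$

Confirmation is advisory: a failed flag is reported, not fatal — it
validates reproducibility rather than steering the search.

## The two-stage driver

Stage 1 screens all factors on a coarse grid. The refinement rule then
fixes categorical factors at their best level, fixes a *structural*
factor (model-capacity factors such as hidden-layer count, flagged in
`factor_spec()`) when its best level is the smallest (shrinking capacity
further risks hurting the model), and re-levels every other numeric
factor to $\{c - s, c, c + s\}$ where $c$ is the stage-1 best and $s$ is
half the stage-1 spacing (integer factors round $s$, erroring if it
rounds to zero). Refined levels may extend beyond the stage-1 range;
declared hard bounds clip them with a warning. Stage 2 uses L9 when
exactly three 3-level factors advance, otherwise the smallest fitting
catalog array with a warning. Stage-2 predicted values are *not* asserted
to beat stage 1 (the additive model guarantees no such monotonicity);
what is tested instead is that on a noise-free additive objective whose
optimum lies inside the refined ranges, the stage-2 confirmation mean is
at least the stage-1 one.

Every evaluation gets a seed derived arithmetically from
(stage seed, run, replicate), so a whole two-stage run is reproducible
byte-for-byte and each evaluation is logged exactly once; total cost is
$a_1 r_1 + r$ plus $a_2 r_2 + r$ evaluations.

## Objectives and synthetic data

Three objectives implement the common contract
`f(assignment, replicate, seed)`:

* **Replay** (`lookup_objective()`, `replay_objective()`) — serves
  recorded responses, used to drive the full pipeline over the bundled
  worked-example tables.
* **Synthetic additive** (`synthetic_additive_objective()`) — baseline
  $+$ per-factor level effects $+\,\mathcal N(0,\sigma^2)$, clipped to
  $(10^{-6}, 1]$, with a unique optimum known by construction. Defaults
  mirror the worked example's regime: baseline 0.5, two dominant factors
  (effect 0.16, with the runner-up level well separated at $+0.08$) and
  minor factors (effect 0.04); the default noise is zero so the additive
  structure is exact. For numeric factors, effects interpolate linearly
  between declared levels (flat beyond them) so refined off-grid
  settings remain defined. What it does *not* emulate: interactions,
  level-dependent noise, and the bimodal collapse real network training
  exhibits (runs that fail to converge at chance accuracy) — passing
  recovery tests here shows the DOE machinery is correct, not that any
  particular model is tunable.
* **MLP** (`mlp_objective()`) — wraps the `nnet` feed-forward trainer
  over a fixed, z-scored train/test split; replicates differ only in the
  weight-initialization seed (the split seed is separate, so
  split-resampling replication is also available). `nnet` fits a single
  hidden layer with logistic activation by BFGS-type optimization, so
  layer counts beyond 1 only select the node count, and the activation /
  optimizer / learning-rate / momentum fields are interface parameters
  consumed only by backends that define them. The training iteration
  budget (`maxit`, default 100) is deliberately a parameter: no
  convergence budget is canonical for this task.

The tabular generator (`generate_synthetic_cvd()`) emulates a
cardiovascular-disease screening cohort: banded draws matching the
printed band frequencies of the 70,000-record Kaggle CVD cohort (age in
days, height, weight, systolic/diastolic pressure, with uniform jitter
within bands — the exact within-band law is a repo choice) and
categorical draws for gender (≈65% female), cholesterol, glucose,
smoking, alcohol and activity. The outcome follows a logistic model on
z-scored features; the intercept is calibrated by root finding so the
expected prevalence is 50%, matching the cohort's near-balanced outcome.
Features are sampled independently — real cohorts correlate weight with
height and pressure with age, so classifiers trained on this generator
see a somewhat easier covariance structure than reality. The Bayes
accuracy of the generating model is stored on the dataset, enabling
closed-form checks of downstream classifiers.

## Numerical and scale choices

* F quantiles and p-values come from R's F distribution (`qf`/`pf`),
  wrapped as `f_quantile()`/`f_pvalue()` with upper-tail orientation.
* Responses are kept on the accuracy scale in $(0,1]$; a floor of
  $10^{-6}$ keeps the larger-the-better SN defined.
* The SS decomposition $SST = \sum SS_f + SSE$ is tested to $10^{-10}$
  relative tolerance; exact-recovery tests on noise-free objectives use
  equality at $10^{-12}$.
* Zero pooled variance yields a zero CI half-width (allowed only when
  $V_e = 0$ exactly); negative variances are impossible by construction.
* Problem sizes in the test-suite: the worked example (18- and 9-run
  designs, 3 replicates), 27-combination brute-force enumerations as
  oracles, a 100-repeat noisy-recovery study at
  $\sigma = 0.25\times$ the smallest retained effect, generator checks at
  $n = 10^4$–$2\times10^4$ rows, and MLP checks at $n = 600$ rows — all
  desk-scale.

## Known limitations

Interactions are not modeled (no linear-graph column allocation); the
procedure is fixed at two stages; dummy-level treatment of mixed-level
factors is rejected rather than supported; and confirmation uses the
normal-theory interval above, which leans on the pooled-error variance
being well estimated — with very few error DF ($\nu_2 = 4$ in a 9-run
stage) the interval is fragile to rounding of $V_e$, which is why
reports carry full-precision values and round only for display.
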