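---
title: "Transitional ordinal models and power simulation for segmental motor scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transitional ordinal models and power simulation for segmental motor scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Upper Extremity Motor Scores (UEMS) grade ten key arm/hand muscles — one
per spinal segment C5, C6, C7, C8, T1 on each body side — on the ordinal
0–5 muscle-contraction scale of the ISNCSCI exam.  Trials in cervical
spinal cord injury routinely collapse this multivariate ordinal endpoint
into a summed total (0–50) or its change from baseline and apply
t-tests or ANCOVA.  Summation assumes equal differences between adjacent
grades and unidimensionality across muscles; neither holds for ordinal
scales, and the practical costs are biased estimates and lost power.

`ordtrial` implements an alternative: a *transitional* cumulative-logit
model fitted at the level of single muscles, together with a trial
simulator and Monte-Carlo power machinery that let the summed-score
analyses and the ordinal model be compared under a known generating
process.

## The model

Only muscles strictly *below* a side's motor level (ML) are modelled —
muscles above the level are intact by definition, and the muscle at the
level is handled separately.  For muscle $m$ of participant $i$ at
follow-up,

$$\operatorname{logit} P(Y_{i,m,2} \le k) = \alpha_{k+1} - \eta_{i,m},
\qquad k = 0, \dots, 4,$$

$$\eta_{i,m} = \beta_{\text{lev}}(x_{\text{lev}}) +
\beta_{\text{base}}(y_{i,m,1}) + \beta_{\text{auto}}(y_{i,m-1,2}) +
\beta_{\text{trt}} x_{\text{trt},i}.$$

* $x_{\text{lev}}$ is a 10-level nominal factor coding the combination
  of motor level and distance (in key muscles) below it: C5 contributes
  distances $-1..-4$, C6 $-1..-3$, C7 $-1,-2$, C8 $-1$; reference
  `C5.-1`.
* $y_{i,m,1}$ is the muscle's own baseline score (ordered factor,
  dummy-coded against level 0).
* $y_{i,m-1,2}$ — the *autoregressive* term — is the **follow-up** score
  of the muscle just rostral, which propagates the anatomical gradient
  of impairment down the cord.
* $x_{\text{trt}}$ is the arm indicator; $e^{\beta_{\text{trt}}}$ is the
  conditional odds ratio between arms.

### Sign convention

Cumulative-logit models are written in the literature with both signs on
the linear predictor.  This package fixes
$\operatorname{logit} P(Y \le k) = \alpha_{k+1} - \eta$, so *positive*
slopes shift probability mass toward *higher* scores: a positive
$\beta_{\text{trt}}$ means treated muscles recover better, and for two
settings differing only in arm the cumulative log-odds differ by exactly
$\beta_{\text{trt}}$ at every $k$ (a tested invariant).  This matches
the convention of `MASS::polr` ($\zeta_k - \eta$), against which the
fitter is verified.  Descriptions phrased as "odds of achieving up to a
given score" refer to the same quantity with the opposite sign of the
effect; the package consistently reports the shift-toward-recovery
convention.

### Factor coding

`y_base` and `y_auto` enter as dummy indicators against reference level
0, not polynomial contrasts.  The maximized likelihood is invariant to
any full-rank recoding (a tested invariant), so this choice affects only
the coefficient labels, and it keeps identifiability bookkeeping simple:
levels absent from a data set produce no column and are recorded in
`dropped_levels`; an absent reference promotes the smallest observed
level.

## Fitting: numerical choices

The log-likelihood of the cumulative-logit model is jointly concave in
$(\alpha, \beta)$.  The fitter (`fit_proportional_odds()`) therefore
uses damped Newton–Raphson with the analytic gradient and Hessian,
step-halving until the cutpoint ordering and a non-increasing objective
are preserved.  Warm-started permutation refits typically converge in
2–4 iterations, which is what makes the B = 1000 permutation test and
the replicated power studies tractable in plain R.  When a Newton step
fails (near-separated data), the fitter falls back to BFGS on the
unconstrained parameterization $(\alpha_1, \log(\alpha_2-\alpha_1),
\dots)$, which enforces ordering by construction.

Convergence is declared when the gradient sup-norm falls below `gtol`
$\times$ the number of rows (`gtol` defaults to $10^{-6}$).
Separation is flagged when any coefficient exceeds 30 in absolute value;
a flagged fit is never silently used: the permutation test reports it
as a failed result and the power driver counts it as a non-rejection
(or drops it from the denominator if more than 1% of replicates fail,
both counts reported).

Rows are treated as independent given covariates.  The clustering of
muscles within participants is handled where it matters for inference:
the permutation test permutes arm labels at *participant* level, so all
of a participant's rows move together.

## The six-test battery

`run_battery()` applies, in fixed order: Welch t-test on the follow-up
total $Y^*_2$; Welch t-test on the change $Y^{**} = Y^*_2 - Y^*_1$;
stratified independence test on $Y^*_2$; the same on $Y^{**}$; ANCOVA of
$Y^*_2$ on arm and $Y^*_1$; and the transitional permutation test.

* **t-tests** are Welch (unequal variances), two-sided.  The variance
  flavour is a convention; Welch is the safer default and produces the
  fractional degrees of freedom familiar from trial reports.
* **Stratified independence tests** use the within-stratum linear
  statistic $T = \sum_s \sum_{i \in s:\,\text{trt}} y_i$, standardized
  by its conditional permutation mean and variance given the stratum
  margins, with a standard-normal reference by default and within-
  stratum Monte-Carlo relabeling as an option.  Identity scores (raw
  sums, not ranks) are the default.  Strata are the left/right
  motor-level constellation (`"C5/C6"`); `strata = "higher_level"`
  collapses to the more rostral of the two levels.  Strata with fewer
  than two participants or with one arm only carry no information and
  drop out of $T - E$ and $V$ alike.
* **Transitional permutation test**: the observed
  $\hat\beta_{\text{trt}}$ is referred to its distribution over `B`
  participant-level relabelings (default 1000), with the add-one
  p-value $(1 + \#\{|\hat\beta^*| \ge |\hat\beta|\})/(B+1)$, which
  avoids exact zeros and makes the test valid at finite `B`.
  Rejection in the power driver is $p \le \alpha$, which matters for
  this discrete p-value.

## The synthetic population

The simulator needs a *reference population*: constellation
frequencies, baseline-score pools per constellation, at-level follow-up
frequencies, and the spontaneous-recovery coefficients.  Real reference
cohorts of this kind are not redistributable, so
`make_synthetic_population()` generates one; it is a first-class,
tested module, not a test fixture.  Its defaults were fixed once, by
checking qualitative fidelity to what is reported about cervical SCI
recovery — *before* any acceptance measurement, and they are not tuned
to test outcomes:

* **Motor levels.** Marginals 0.40/0.25/0.15/0.10/0.10 over C5..T1 per
  side, with a concordance boost (log-weight +2) for equal left/right
  levels; the (T1,T1) cell is structurally zero since such participants
  have no below-level muscle.
* **Baseline pools** (50 vectors per constellation): above-level
  muscles intact (5); at-level muscles moderate (mass on 3–5,
  reflecting the exam's definition of the motor level); below-level
  muscles a spared/weak mixture whose sparing probability decays with
  distance (0.35/0.25/0.18/0.12).  How baseline is filled at and above
  the level is a documented convention — the exam definition implies
  it, but reference descriptions do not state it.
* **Coefficients.** Cutpoints (−0.2, 1.0, 2.0, 3.0, 4.2); distance step
  −0.5 and level step −0.15 on $\beta_{\text{lev}}$; +0.5 per baseline
  level; +0.5 per autoregressive level.  Under these values the
  generated world shows a clean distance gradient in mean follow-up
  score (2.98 / 2.06 / 1.47 / 0.96 at distances 1–4), every outcome
  category populated (10–26%), and spontaneous recovery (mean total
  UEMS 23.7 at baseline → 28.5 at follow-up).

Simulation of one participant proceeds rostral→caudal per side:
above-level muscles are set to 5; the at-level muscle is drawn from the
segment-specific at-level frequencies (unconditionally on its baseline
— the reference procedure reads unconditional — and identically in both
arms); each below-level muscle is drawn from the transitional model
conditioning on its own baseline and the just-drawn rostral follow-up
score, with $\beta_{\text{trt}}$ added for treated participants.
Allocation is exact 1:1 (random permutation), the conventional reading
of "1:1 allocation".

Every draw consumes exactly one uniform deviate, and the consumption
order depends only on motor levels.  Control-arm participants are
therefore **byte-identical across treatment-effect settings** under the
same seed — a tested invariant that pins down the claim "the control
arm's law does not depend on $\beta_{\text{trt}}$" exactly rather than
statistically.

What the generator does *not* emulate: dropout and missingness,
visit-time variation, cross-side dependence beyond the shared
constellation and baseline vector, floor/ceiling measurement artifacts,
and any real cohort's idiosyncratic frequencies.  A green power result
on this world demonstrates correct machinery and the qualitative
ordering of methods under a model-true process; it does not certify
power magnitudes for any real trial.

## Power machinery

`run_scenario()` simulates replicate trials, applies the battery, and
reports per-method rejection fractions with Wilson score intervals at
95% (the confidence level that reproduces the reference table's
printed intervals).  Replicate $r$ runs on a child seed derived
deterministically from the root seed, so results are independent of
execution order.  `run_grid()` crosses sizes × effects; the reference
design is 7 sizes (50–200) × 6 effects (log OR 0 to log 1.5), 42
scenarios at 1000 replicates each.  A desk-scale profile (300
replicates, B = 199) is what the acceptance tests and `--fast` CLI
profile use.  Contour-style smoothing of the grid is deliberately not
reproduced — the export is the raw grid; smoothing is presentation.

## Design choices on open points

* **Strata for the i-tests**: "the motor level of a participant" is
  ambiguous with two sides; the default is the full left/right
  constellation, with `higher_level` as the exposed alternative.
* **i-test reference**: asymptotic normal with identity scores by
  default, Monte-Carlo as option; which the original framework used is
  not stated, both are provided.
* **Warm starts**: permutation refits start from the observed optimum.
  Since the objective is concave with a unique optimum, warm starting
  changes the path, not the answer; the suite spot-checks fits against
  `MASS::polr` and a grid-search oracle.
* **Missing data**: transitional rows with any missing component are
  dropped row-wise; summed-score tests require complete 10-muscle data
  per participant (exclusions counted).  With long-format-only input
  the summed-score tests operate on below-level sums, recorded in
  `detail$totals_scope`.
* **YAML** configs were considered and dropped (no parser available in
  the target environment); configs are JSON.

## Known limitations

* The likelihood ignores within-participant correlation (working
  independence); standard errors from a single fit are therefore not
  trustworthy — inference should go through the permutation test, as
  implemented.
* Asymptotic i-test p-values with many tiny strata lean on the CLT
  across strata; the Monte-Carlo mode exists for small or unbalanced
  trials.
* Power magnitudes are population-dependent.  Only parameter-free
  quantities (Wilson cells, structural constants, type-I error,
  parameter recovery, oracle equivalences, the power *ordering*) are
  asserted by the test suite; no power magnitude from the reference
  design is claimed.
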