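# ordtrial

Autoregressive transitional ordinal models and Monte-Carlo power
simulation for segmental motor-score endpoints in two-arm randomized
trials.

## The problem

Upper Extremity Motor Scores (UEMS) grade ten key arm/hand muscles (one
per spinal segment C5–T1, both body sides) on the ordinal 0–5
muscle-contraction scale of the ISNCSCI exam.  Trials in cervical spinal
cord injury usually sum them into a 0–50 total — or its change from
baseline — and apply t-tests or ANCOVA, which assumes equal differences
between adjacent ordinal grades and unidimensionality across muscles.
This package is for trial statisticians and methodologists who want to
analyse such endpoints at the muscle level instead, and to quantify what
the summed-score shortcut costs in statistical power.

## The model

For each muscle strictly below a side's motor level (ML), the follow-up
score is modelled by a cumulative-logit proportional-odds regression
with a transitional, autoregressive structure:

    logit P(Y[i,m,2] <= k) = alpha[k+1] - ( beta_lev(x_lev)
                                          + beta_base(y[i,m,1])
                                          + beta_auto(y[i,m-1,2])
                                          + beta_trt * x_trt )

where `x_lev` is the 10-level motor-level/distance factor (`C5.-1` ...
`C8.-1`), `y[i,m,1]` the muscle's own baseline score, `y[i,m-1,2]` the
*follow-up* score of the muscle just rostral (the autoregressive term
that propagates impairment down the cord), and `exp(beta_trt)` the
conditional odds ratio between arms.  Positive `beta_trt` shifts
probability mass toward higher scores.  Inference on `beta_trt` is by a
participant-level permutation test (default 1000 relabelings), which
respects the clustering of muscles within participants.

Around the model the package provides: a synthetic reference-population
generator (stand-in for non-distributable observational cohorts), a
trial simulator following the population's constellation frequencies,
baseline resampling pools and at-level frequencies, a six-test analysis
battery (t-test, t-test on change, stratified independence tests on
both, ANCOVA, transitional permutation test), and a power-study driver
with Wilson score intervals.

## Worked example

```r
library(ordtrial)

pop   <- make_synthetic_population(seed = 1)            # reference population
trial <- simulate_trial(pop, n_total = 150, beta_trt = log(1.3), seed = 4)

set.seed(4)
run_battery(trial, config = list(permutations = 999))
```

```
Treatment-effect test battery
t_test       statistic=  0.3539  p=0.7239
t_test_delta statistic=  2.1350  p=0.0346
i_test       statistic=  2.5504  p=0.01076
i_test_delta statistic=  2.1381  p=0.03251
ancova       statistic=  1.7512  p=0.08199
transitional statistic=  0.3048  p=0.017
```

A true odds ratio of 1.3 was simulated.  The t-test on the raw follow-up
total misses it entirely (p = 0.72); the baseline-adjusted and
stratified summed-score tests are borderline; the transitional model
recovers the effect (β̂ = 0.305, OR ≈ 1.36, close to the simulated
log 1.3 = 0.262) with a permutation p-value of 0.017.

```r
fit_proportional_odds(build_transitional_rows(trial), include_treatment = TRUE)
#> Transitional proportional-odds fit
#>   rows: 957   logLik: -1426.644   converged: TRUE
#>   beta_trt: 0.3048 (OR 1.356)

plot_score_shift(pop$coefficients, "shift.pdf")   # control vs treatment panels
#>               0     1     2     3     4     5
#> control   0.231 0.269 0.231 0.150 0.080 0.039
#> treatment 0.188 0.247 0.242 0.174 0.099 0.050
```

The score-shift matrix is for the default constellation (C8 muscle under
a C5 motor level, baseline 1, rostral follow-up 3, OR 1.3): low scores
lose mass, high scores gain — the clinical reading of a positive
conditional odds ratio.

Power studies follow the same pattern:

```r
tab <- run_scenario(pop, n_total = 150, beta_trt = log(1.3),
                    n_replications = 300, seed = 102,
                    config = list(permutations = 199))
tab[, c("method", "power", "wilson_low", "wilson_high")]
```

which on this synthetic population estimates the transitional test's
power at 0.58 against 0.22–0.44 for the summed-score approaches
(`wilson_interval(50, 1000)` → 0.038–0.065 reproduces the reference
interval arithmetic).  `run_grid()` crosses the full 7 × 6 = 42 scenario
design.

## Command line

```sh
Rscript inst/cli/ordtrial simulate --n 100 --beta-trt 0.2624 --seed 7 --out trial.csv
Rscript inst/cli/ordtrial analyze  --data trial.csv --format wide --permutations 1000 --out report.json
Rscript inst/cli/ordtrial power    --fast --sizes 50,100 --effects 0,0.2624 --out power.csv
Rscript inst/cli/ordtrial plot-shift --out shift.pdf
```

(after installation, resolve the script with
`system.file("cli/ordtrial", package = "ordtrial")`).

## More

The methods vignette (`vignettes/transitional-ordinal-power.Rmd`)
documents the model and its assumptions, the synthetic world and what it
does and does not emulate, numerical choices in the fitter, and known
limitations.
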