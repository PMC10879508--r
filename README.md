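# dgcm — discontinuous growth curve models for experience-sampling well-being data

`dgcm` is an R package for researchers who study how daily well-being
responds to a collective event — an invasion, a disaster, a lockdown — using
experience-sampling (EMA) data: several random short surveys a day over
individually staggered multi-week participation windows. It implements the
full analysis chain around the outbreak of the Russo-Ukrainian war on
2022-02-24 as a reusable, tested pipeline, and ships a synthetic-data
generator that emulates the design so everything can be exercised and
validated without the original data.

## The model

Daily affective well-being (mean of 3 positive-affect and 3 reverse-scored
negative-affect items, z-standardized across all state measurements, then
averaged per participant-day) is modelled with discontinuous growth curves.
Each date is coded with four change parameters with a per-day increment of
1/31: `time = d/31`, `level` (−1 before the event, 0 after),
`pre_event` (= time before the event, else 0) and `post_event` (= time after
the event, else 0), where `d` is the day distance to the event. The richest
model of the eight-model family ("2d") is, for day *i* of person *j*,

```
WB_ij = β'_0j + β'_1j pre_i + β'_2j post_i + β'_3j level_i + ε_ij
β'_kj = β_k + b_kj,    b_j ~ N(0, Σ) (unstructured),   ε_ij ~ N(0, σ²)
```

fitted by full maximum likelihood (profiled grouped marginal likelihood with
an analytic gradient, implemented in C++). The eight models (every
combination of change parameters from none up to pre+post+level, always with
random slopes on the included terms) are compared by AIC. The winner can be
moderated by a standardized person-level covariate — e.g. the personality
meta-trait Stability, `(A + C + (6 − N))/3` — entering the intercept and
every slope. Daily war salience (worldwide "Ukraine" tweet counts,
z-standardized across days) is analysed as a Level-1 predictor, optionally
split into a between-person component (`bs`, the person's mean salience over
their observed days) and a within-person component (`ws`, the daily
deviation).

## Worked example

Generate a study-scale synthetic dataset (1,300 participants, ~4-week
staggered windows, truths set to the headline estimates of the emulated
study), preprocess it, compare the trajectory family, and moderate the
winner by Stability:

```r
library(dgcm)

sim  <- generate(generator_config(), seed = 42)
prep <- prepare_daily(sim$states, sim$participants)
fam  <- fit_family(prep$daily)
fam
#> Trajectory model family (AIC comparison, best first)
#>  model    loglik  k      aic converged delta_aic rank
#>     2d -17215.65 15 34461.30      TRUE      0.00    1
#>     2b -17227.11 10 34474.23      TRUE     12.93    2
#>     1d -17274.35 10 34568.69      TRUE    107.39    3
#>     ...
#> winner: 2d - pre-event trend, level change, and post-event trend

moderate(prep$daily, prep$traits, "stability")
#>                  term      b    se      z     p ci_low ci_high
#>           (Intercept) -0.099 0.023 -4.328 0.000 -0.143  -0.054
#>             pre_event -0.034 0.039 -0.877 0.380 -0.112   0.043
#>            post_event  0.021 0.035  0.585 0.559 -0.048   0.090
#>                 level -0.180 0.032 -5.693 0.000 -0.242  -0.118
#>             stability  0.211 0.023  9.223 0.000  0.166   0.255
#>   pre_event:stability -0.003 0.039 -0.078 0.938 -0.079   0.073
#>  post_event:stability  0.201 0.035  5.678 0.000  0.132   0.271
#>       level:stability -0.115 0.031 -3.646 0.000 -0.176  -0.053
```

The AIC winner is the generating model: a sudden drop of ~0.18 SD in
well-being on the event day (`level`), no credible anticipation slope, and a
recovery slope that is strongly moderated by Stability — people one SD above
the mean recover ~0.2 SD more over the post-event month. The salience models
read analogously:

```r
sim2  <- generate(generator_config(scenario = "salience"), seed = 42)
prep2 <- prepare_daily(sim2$states, sim2$participants)
rows  <- decompose_ws_bs(join_salience(prep2$daily,
                                       standardize_salience(sim2$salience)))
fit_salience_model(rows, decomposed = TRUE)
#>         term      b    se      z     p ci_low ci_high
#>  (Intercept)  0.004 0.016  0.235 0.814 -0.027   0.035
#>           ws -0.071 0.008 -8.784 0.000 -0.086  -0.055
#>           bs -0.089 0.028 -3.135 0.002 -0.144  -0.033
```

i.e. well-being is lower on a person's higher-salience days (`ws`) and lower
for people whose participation fell in higher-salience weeks (`bs`).

End-to-end report bundles (comparison table, coefficient CSV/JSON files,
exclusion report, manifest) are written by `run_main_analysis()` /
`run_salience_analysis()` from CSV inputs; `write_dataset()` materializes a
generated dataset in the same CSV layout. To analyse the original study's
deposited data, point `run_config()` at its state, participant and salience
tables (mapping column names via the `schema` argument if they differ).

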