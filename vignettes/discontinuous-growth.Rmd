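---
title: "Discontinuous growth curve models for experience-sampling well-being data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discontinuous growth curve models for experience-sampling well-being data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a collective event — here, the Russian invasion of Ukraine on
2022-02-24 — interrupts ordinary life, daily well-being may show an
anticipatory trend before the event, an abrupt level shift on the event day,
and a gradual recovery (or worsening) afterwards. Experience-sampling data
(up to four random beeps a day over ~4-week individual participation
windows) make these components estimable, but require careful preprocessing,
an explicit coding of event time, and multilevel models that separate
within-person change from stable between-person differences.

`dgcm` implements that full chain: ingest and quality filtering of
state-level affect reports, standardization and daily aggregation, the
change-parameter coding, maximum-likelihood estimation of
random-intercept–random-slope linear mixed models, AIC comparison of an
eight-model trajectory family, cross-level moderation by personality
meta-traits, and within-/between-person decomposition of a daily
event-salience series (worldwide tweet counts). A synthetic-data generator
reproduces the design so every stage is testable without access to the
original data.

## Measures and preprocessing

State well-being at a beep is the mean of three positive-affect items and
three reverse-scored (`7 - x`) negative-affect items, each on a 1–6 scale.
Scores are z-standardized **across all retained measurement points** and
then averaged within participant-days; model coefficients are therefore in
units of the state-level standard deviation.

Three exclusion rules are applied in order, each participant attributed to
the first rule that removes them: (a) self-declared non-conscientious
responding, (b) less than two seconds per item in the pre-survey,
(c) state data on fewer than two distinct days inside the analysis window
(two days are the minimum for any within-person variance on the change
parameters). Two decisions here were genuinely open and are fixed as
follows:

* rule (c) counts days **inside the analysis window**, because only those
  days carry change-parameter variance;
* standardization uses the **post-exclusion** sample, so that the unit of
  analysis equals the unit of the modelled population.

The meta-trait Stability is `(A + C + (6 - N)) / 3` from the BFI-2 domain
scores (reverse-keying of items is assumed done upstream), Plasticity is
`(E + O) / 2`; both are z-standardized across included participants.

## Event-time coding

With `d` the signed day distance to the event and a per-day increment of
`1/31` (fixed by the 31-day half-width of the main window):

| parameter | value | interpretation |
|---|---|---|
| `time` | `d/31` | secular linear trend |
| `level` | `-1` if `d < 0`, else `0` | baseline shift on the event day |
| `pre_event` | `d/31` if `d < 0`, else `0` | anticipation slope |
| `post_event` | `d/31` if `d > 0`, else `0` | recovery slope |

`time = pre_event + post_event` always; the event day itself belongs to the
post-event baseline (all four codings zero). The increment stays `1/31` for
the narrow (±7 d) and broad (±54 d) windows, so slope coefficients stay
comparable; the broad window's extreme codings are ±54/31 ≈ ±1.742.

## The estimator

All models are two-level Gaussian mixed models, fitted by full maximum
likelihood (not REML, so AICs are comparable across different fixed-effect
structures). For participant *j* with response vector `y_j`, fixed design
`X_j` and random design `Z_j`,

$$y_j \sim N(X_j\beta,\; Z_j \Sigma Z_j^\top + \sigma^2 I).$$

`Sigma` is unstructured (variances and correlations). Internally the
likelihood is profiled: writing `G = Sigma/sigma^2 = LL'` with `L` a
log-Cholesky-parameterized lower triangle, `beta` has a closed GLS form and
`sigma^2` a closed ML form at every `G`, so the optimizer works on the
`q(q+1)/2` free elements of `L` only. The per-group Woodbury identity
reduces every evaluation to `q x q` operations on pre-computed
cross-products, and the exact gradient of the profiled deviance (an
envelope-theorem calculation) is supplied to the quasi-Newton search.
Numerical choices:

* three deterministic starts (unit, 0.1, 3 × residual scale) guard against
  boundary optima; the best optimum is kept, so fits are deterministic;
* log-scale diagonals are bounded in `[-12, 6]`: a variance component can
  collapse to ~0 without leaving the feasible region;
* a smallest-to-largest eigenvalue ratio of `Sigma` below `1e-8` raises a
  boundary warning, not an error;
* Wald inference uses the standard-normal reference (`ci95 = b ± 1.96 se`),
  appropriate with thousands of residual degrees of freedom; no
  Satterthwaite machinery;
* `AIC = 2k - 2logLik` with `k = p + q(q+1)/2 + 1`, and the full
  `-(N/2)log 2π` constant is kept in the log-likelihood so AICs are
  comparable with other software.

The exported `marginal_loglik()` is an independent dense per-group
evaluation of the same likelihood and serves as the in-package oracle for
the profiled path; the test suite additionally cross-checks whole fits
against `lme4` and against closed-form estimators on balanced designs.

## The trajectory family and moderation

Eight models combine the change parameters (`1a` empty, `1b` level,
`1c` post, `1d` post+level, `2a` time, `2b` time+level, `2c` pre+post,
`2d` pre+post+level), each with a random intercept and random slopes on all
its Level-1 terms. They are fitted on identical rows and ranked by AIC;
ties closer than `1e-6` go to the model with fewer parameters (parsimony,
which is what AIC is for). A person-level moderator (Stability, Plasticity,
or a sociodemographic covariate, standardized across participants) enters
the winner with a main effect and one cross-level interaction per change
parameter — never with random effects of its own, and one covariate per
model.

## Salience models

Daily worldwide "Ukraine" tweet counts are z-standardized across window
days (tweet days are UTC; daily well-being keeps its local calendar date,
and the join is by date label — the one-hour-grade mismatch this can induce
is far below the daily resolution of the series). The decomposition per
participant-day is `bs` = the person's mean standardized salience over the
days **they actually participated**, `ws` = the daily deviation from it, so
`ws + bs` reconstructs the standardized salience exactly and person-means
of `ws` are zero. The decomposed model gives `bs` a fixed effect only: a
between-person constant cannot carry within-person random variation, so the
random part is intercept + `ws` slope. A lagged variant pairs well-being on
day *t* with salience on day *t−1*; the first window day then has no
predecessor and is dropped.

## The synthetic-data generator

`generate()` draws a full dataset under a configurable truth. It emulates:
staggered 28-day participation windows (uniform start dates over
2021-12-28 … 2022-03-27, truncated to the 63-day analysis window), up to 4
beeps/day with i.i.d. per-beep compliance 0.25 (≈13 observed days per
person, matching the ~17,990 daily scores from ~1,341 participants in the
emulated study), latent daily well-being following the `2d` trajectory with
person-level random effects and Stability-moderated slopes, discretized 1–6
item responses (PA items as a noisy rounded copy of the latent state, NA
items as the `7 − x` reversal of a second noisy copy, so the scoring step
approximately inverts generation), and an event-spiked salience series
(baseline, exponential decay after the event, non-negative noise). Beep
observation is decided *before* well-being is drawn (compliance independent
of well-being), and the generator's `ws`/`bs` are computed over observed
days — the same definition the analysis uses.

Default fixed effects and moderation effects are the headline estimates of
the emulated study (level −0.200, pre 0.005, post 0.089, Stability main
0.245, Stability×post 0.161; salience scenario ws −0.065, bs −0.116).
Because those truths are in standardized units, each scenario's noise
components are calibrated analytically so the total state-level variance is
≈1 (verified at 0.98–1.01 by simulation); fitted coefficients then estimate
the configured truths without a rescaling bias.

The random-effect variances are not reported by the emulated study and were
the main free design choice. Two considerations fix them. First, with only
~14 observed days per person, within-person time variation is small, so
slope variances are weakly identified; slope SDs of 0.6 make the generating
`2d` structure reliably identifiable by AIC at the study's sample size
while leaving a plausible day-level residual (SD 0.32) under the
unit-variance budget. Second, the correlation structure couples a steeper
event-day drop, and a steeper anticipatory decline, with stronger recovery
(`corr(level, post) = corr(pre, post) = −0.3`) — the substantively expected
"dip-and-rebound" pattern, which also separates the independent pre/post
slopes of `2d` from the single secular slope of `2b`.

What passing tests on these data do **not** show about real data: the
generator has no informative missingness (compliance is independent of
well-being), no country structure, no weekday or within-day cycles, no
heavy-tailed or skewed affect distributions, and its residual
heteroscedasticity is only the mechanical 1/beeps-per-day kind. Recovery of
the configured truths demonstrates correctness of the estimator and
pipeline, not robustness to those real-world features.

## Problem sizes and simulation design

The simulation-based checks use the emulated study's scale — 1,300
generated participants (≈17,000 daily scores) — with 20 Monte-Carlo seeds
for parameter-recovery and model-selection studies; recovery is judged
against 3 Monte-Carlo standard errors of the seed means. Smaller unit
fixtures (20–400 participants) exercise the same code paths where scale is
irrelevant.

## Known limitations

* One event per dataset; no quadratic or spline time codings.
* ML only (REML is deliberately out: AIC comparability), Gaussian outcomes
  only, no crossed random effects.
* p-values and CIs are Wald/normal; with few participants they would be
  anti-conservative — the intended regime is hundreds of participants.
* The exclusion report counts rules in fixed order a→b→c; participants
  failing several rules are attributed to the first.
* Real-data idiosyncrasies (technical outages, language differences,
  retrospective-entry artifacts) are out of scope for the generator.
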