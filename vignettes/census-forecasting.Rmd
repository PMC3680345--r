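---
title: "Ensemble census forecasting: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble census forecasting: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censuscast)
```

This vignette is the package's account of the science behind its forecasts:
the models and the assumptions they rest on, the parameters a user can turn
and what they mean, the numerical conventions in corner cases, and what the
synthetic experiments do and do not demonstrate about real hospital data.

## The census identity and the day convention

The end-of-day census obeys an accounting identity: the census `k` days ahead
equals today's census plus all interim arrivals minus all interim departures.
Only the current census is observed; forecasting reduces to predicting the two
flows. Two structural assumptions are inherited by everything downstream:

* arrivals and departures on the same day are independent — sensible while
  the unit runs below capacity, wrong if admissions are rationed by bed
  availability;
* departures depend on earlier arrivals only through how many patients are
  present (no competing-risk structure; non-healthy discharge such as death or
  transfer is out of scope).

A patient admitted on day `a` with length of stay `L` appears in the
end-of-day census on days `a, …, a+L−1`; the day of stay is `s = day − a`
(admission day is `s = 0`), and the departure is recorded in the flow of day
`a+L`, the first day the patient is absent. This convention makes the
departure label `Y^(k,s) = 1{LOS ≤ k+s}` coincide exactly with "absent from
the census at the end of day `t+k`", which is what the census identity sums.
Sub-day stays (`los = 0`) are rejected, mirroring the >24-hour inclusion rule
of the data the method was designed for. Whether a departing patient is
removed before or after the 11:59pm snapshot is not decidable from an
end-of-day ledger; the convention above is one consistent reading and is
applied uniformly to training labels, census reconstruction and scoring.

A record censored at `c` days means `LOS > c`: the patient was still present
at day of stay `c`. Training labels are used only where the censoring bound
determines them (`y = 0` requires `c ≥ k + s`); indeterminate labels are
dropped, never imputed.

## Arrivals: seasonality-adjusted Poisson autoregression

Daily arrival counts follow a log-linear Poisson model whose linear predictor
combines `p` lagged counts with `K` harmonic seasonality terms
(cosine/sine pairs at frequency `ω_k` cycles per series length `T`).
Parameters are estimated by conditional maximum likelihood — the first days
act as fixed initial conditions — via iteratively reweighted least squares
with step-halving; the parameter covariance is the inverse observed Fisher
information at the optimum (for the Poisson log link, observed and expected
information coincide on the fixed design).

Tunable parameters and their defaults:

* `order` (`p`, days of autoregression): selected by BIC over `p = 0..p_max`.
  All candidate orders are conditioned on the same first `p_max` days so their
  likelihoods are comparable; the effective sample size in the BIC penalty is
  `T − p_max`, and ties break toward the smaller order. A common window is a
  choice, not a theorem — without it, BIC values across orders are not on the
  same data.
* `harmonic` frequency: chosen as the periodogram argmax of the mean-centered
  series over integer candidate cycle counts. This automates what is usually
  a visual inspection of the autocorrelation function; on a series with no
  real seasonality the argmax is still returned, and the caller decides
  whether to keep `K = 0`. Frequencies are indexed in cycles per series
  length, so a frequency of 3 over roughly 18 months is one cycle per 26
  weeks. In the expanding-window backtest the harmonic specification is
  frozen at the first refit and only coefficients are re-estimated: because
  `ω` is indexed against `T`, re-selecting it as the window grows would
  silently change the period.
* `K` (number of harmonics, default 1): both the cosine and sine amplitude
  are always fitted per harmonic, keeping the phase free.

## Departures: stratified discrete-time logistic models

For each forecast horizon `k` and each day-of-stay stratum
`s ∈ {0, 1, …, R−1, ≥R}` (default `R = 10`), the probability that a patient
departs within `k` further days is a logistic regression on the covariates
available at day of stay `s`: birth weight and gestational age at `s = 0`;
day-1 severity scores from `s ≥ 1`; the day-3 score from `s ≥ 3`; the day-7
score from `s ≥ 7`. The stratum `s = 0` is modelled even though severity
scores do not yet exist there — newly admitted patients are in the census and
must have a departure probability. The pooled `≥R` stratum contributes one
row per (patient, day of stay) pair, using the covariate set available at
`s = R`.

Numerical choices, all of which matter only in sparse strata:

* a small ridge penalty (default `1e-4`) on non-intercept coefficients guards
  against separation; at this magnitude it is numerically invisible on
  well-conditioned strata (the unpenalized fit is recovered to ~1e-5, which
  the tests check against an independent logistic fit);
* strata with fewer than 10 usable rows, no outcome variation, or a failed
  fit fall back first to a refit pooled with the adjacent smaller-`s`
  stratum on the intersection covariate set, then to an intercept-only model
  at the empirical event rate clamped to `[1/(n+2), 1−1/(n+2)]`, whose
  variance comes from the binomial information at the clamped rate (capped
  when there is no data at all). Every fallback is flagged in the fit
  diagnostics;
* the link is logit; the machinery is agnostic to that choice but no other
  link is exercised by the tests.

## The ensemble

Each of `M` realizations (default 1000; the evaluation experiments use 200)
draws the arrival parameter vector and every `(k, s)` coefficient block from
their asymptotic multivariate normal distributions, simulates arrivals
sequentially (lags beyond the origin use previously simulated counts), draws
one Bernoulli departure indicator per in-census patient, and for each interim
day resamples that day's simulated arrivals as pseudo-subjects — baseline
covariates drawn jointly with replacement from the training pool — whose
departure-within-`k−j` indicators come from the day-of-stay-0 model. Arrivals
on the target day itself cannot have departed and draw no indicator.

Design choices worth knowing:

* Departures are handled as cumulative within-`k` indicators: each requested
  horizon gets its own draws, and intermediate census values are not chained
  within a realization. This avoids double counting that a day-by-day
  departure series would require bookkeeping to prevent; the cost is that a
  single realization's trajectory across horizons is not a coherent sample
  path (the per-horizon marginals, which the intervals summarize, are).
* Coefficient draws are independent across `(k, s)` blocks; the models are
  fitted separately and no cross-block covariance is estimated. This ignores
  the correlation induced by shared patients across horizons and is a known
  limitation.
* Per-horizon departure draws are independent across `k` within a
  realization; an optional shared-uniform coupling could enforce monotone
  departures across horizons but is not the default, matching the procedure
  as published.
* Point forecast is the ensemble median (configurable to the mean); intervals
  are empirical percentiles using the default type-7 interpolation of
  `quantile()`.
* Reproducibility: one master seed; realization `r` derives substream seed
  `(seed + 48271·r) mod 2147483397 + 1`, so results are bit-identical across
  runs and enlarging `M` never reshuffles earlier realizations.
* Linear predictors are clipped to `[−30, 30]` before exponentiation, and
  simulated Poisson means are additionally capped at `1e7`: extreme normal
  parameter draws can otherwise overflow, and a log-linear autoregression on
  large counts (notably the census-only benchmark, where lagged values are
  census-sized) has an unstable regime in which a large simulated count feeds
  an even larger mean. The cap keeps such realizations finite; they surface
  as very wide benchmark intervals rather than as errors.

## Backtesting

The continuously-updating backtest forecasts each test day from an expanding
training window: arrival counts up to the origin, patient records censored at
the origin (so the training set absorbs each elapsed test day), refits every
`cadence` days (default 1; the packaged experiments use 7 to trade a little
statistical freshness for a 7-fold cut in fitting cost — the census state,
arrival history and pseudo-subject pool are still updated daily). MAPE is
reported as the mean absolute error in patient counts — on censuses of tens
of patients it is an absolute, not percentage, quantity — with a
normal-approximation 95% CI (mean ± 1.96·SE of the absolute errors; the CI
method is a choice, as none is prescribed). Interval coverage is the fraction
of test days whose observed census falls inside the 95% interval. The
census-only benchmark applies the identical PAR machinery and ensemble
summaries to the census-count series itself, even though a census is not a
pure count-arrival process — that mis-specification is the point of the
comparison.

No information can leak backwards by construction (training data are filtered
by origin day), and the test suite verifies it by injecting a future-dated
sentinel patient and asserting bit-identical forecasts.

## The synthetic generator

`simulate_unit_history()` produces the unit histories every experiment runs
on: seasonal Poisson arrivals (defaults: intercept 0.858, one lag at 0.05,
one harmonic of amplitude 0.18 at 3 cycles per series — about 2.7 admissions
per day), jointly normal birth weight and gestational age (2418 ± 940 g,
34.6 ± 4.0 completed weeks, correlation 0.8, truncated to clinical ranges
with the pre-truncation mean adjusted so realized means hit the targets),
zero-inflated severity scores that worsen with prematurity (day-3 score a
binomially thinned copy of day 1; day-7 morbidity inflated relative to day
1), and length of stay drawn by iterating a discrete-time logistic hazard
`logit h(j) = −3.10 + 0.70 log j − 0.047 j + 0.30·(bw_kg − 2.418) +
0.08·(ga − 34.6) − 0.015·snapdol1 − 0.0006·main1`, capped at 120 days. The
baseline was calibrated once so the marginal LOS distribution is
right-skewed with median 10, mean ≈ 20, sd ≈ 29. Scores exist latently from
admission and are revealed on their collection day; the patient table masks
whatever a realized stay never revealed.

Because the hazard is logistic in the covariates, the one-day departure
models are exactly well specified (`true_departure_prob()` gives the closed
form `1 − Π(1−h)` the fits are tested against); for `k > 1` the cumulative
probability is no longer exactly logistic in `Z`, and strata below `s = 7`
marginalize over scores the hazard uses — a deliberate, mild
mis-specification of the same kind the real data impose. What the generator
does **not** emulate: day-of-week effects, correlated multiple-birth
admissions, capacity feedback on admissions, realistic score dynamics, or
non-healthy discharge. Passing tests therefore demonstrate internal
correctness and calibration under the model family's own assumptions, not
performance on any particular hospital's data.

## Problem sizes and experiment scales

The packaged experiments are sized for a desk machine: the headline
calibration run uses a 560-day history, 100 consecutive forecast origins,
weekly refits and 200-realization ensembles (about 45 seconds), and reports
5-day 95%-interval coverage of 90–100% across seeds. Replicate-based property
checks (error growing with horizon,
benchmark intervals wider than the primary model's) use 20 small backtests
of 8 origins each. Parameter-recovery experiments use series of 2000–3000
days and patient cohorts of ~6500.

## Known limitations

* Point forecasts inherit any bias in the arrival model multiplicatively
  with horizon; on real data a tendency to over- or under-estimate interim
  arrivals propagates into longer forecasts.
* The asymptotic-normal parameter sampling ignores uncertainty in the order
  and frequency selection themselves.
* The pooled `≥R` stratum treats every (patient, day) pair as an independent
  row, understating within-patient correlation in that stratum's fit.
* Pseudo-subject covariates are resampled unconditionally, not by season or
  calendar month.
* No interval recalibration is attempted; intervals are raw ensemble
  percentiles.
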