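---
title: "Forecasting tree pollen season onset from temperature fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting tree pollen season onset from temperature fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenonset)
```

## The problem

Alder (*Alnus*), hazel (*Corylus*) and birch (*Betula*) release their pollen
at the very beginning of the growing season, and in central Europe their
airborne pollen is a leading cause of early-spring allergic rhinitis. For
patients and allergologists, the question that matters is short-range and
binary: *is the season about to start?* Long-range weather prediction for
January–March is unreliable, so `pollenonset` works instead from a pattern
visible in the observed temperature record itself: in most years, a short
period of cooling followed by renewed warming — a dip, or "local minimum",
in a smoothed temperature curve — precedes the onset of each taxon's pollen
season. The package turns that observation into a tested, reusable pipeline:

1. **Feature extraction** — 5-day trailing running means of a daily
   temperature statistic, and detection of local minima in that series.
2. **Season-start determination** — the cumulative pollen sum method applied
   to daily concentrations, with early/moderate/late (E/M/L) season typing
   and the descriptive statistics used to summarise multi-year records.
3. **Model fitting** — a two-predictor logistic regression for the
   probability that the season starts within ten days of a local minimum,
   with the full diagnostic set (Wald statistics, odds ratios, confidence
   intervals, likelihood-ratio goodness of fit).
4. **Verification** — applying frozen coefficients to held-out years and
   scoring the strict `probability > 0.5` forecasts against what happened.
5. **Synthetic data** — a generator producing weather and pollen series with
   the statistical structure the analysis assumes, so that every stage and
   the statistical calibration of the fit can be tested without any
   external data.

## Daily mean and running-mean features

The daily mean temperature is the climatological four-observation average

$$t_{\mathrm{mean}} = \frac{t_{\max} + t_{\min} + t_{06} + t_{18}}{4},$$

with $t_{06}$ and $t_{18}$ the readings at 06:00 and 18:00 UTC. Features
are 5-day *trailing* running means: the value indexed at day $d$ averages
days $d-4, \dots, d$, so the value at January 1 uses December 28 –
January 1. The window is deliberately not centred — a centred window would
peek at days after the indexed one, and the application is prospective
forecasting. Alnus and Corylus use running means of the daily **maximum**
(their series are indexed from January 1); Betula uses running means of the
daily **mean** temperature, indexed from March 5 (window March 1–5), about
forty days before its average season start.

A **local minimum** is a day preceded by at least two strictly decreasing
steps of the running mean and followed by at least two strictly increasing
steps. Two numerical choices deserve a note:

* *Ties are strict.* A flat step terminates a run, so a plateau such as
  (5, 4, 4, 3, 4, 5) contains no local minimum. No tie rule is implied by
  the verbal definition "decrease … then increase"; strict inequalities
  make the detector deterministic and match the mathematical notion of a
  strict local minimum. With real-valued temperatures exact ties are rare,
  so the choice is essentially free in practice.
* *Edges are ineligible.* A day within two positions of either end of the
  available series cannot exhibit both flanks and is never reported,
  rather than being reported on partial evidence.

Gaps of at most two consecutive days in the raw weather record are filled
by per-field linear interpolation (with a warning); longer gaps abort the
year. Years with seriously incomplete records should be excluded, not
patched — interpolating a week of winter weather would manufacture exactly
the kind of smooth dip the detector looks for.

## Season starts from pollen counts

The season start is the first day on which the cumulative sum of daily
pollen concentrations (grains/m³/day), accumulated from January 1 (Alnus,
Corylus) or March 1 (Betula), reaches the taxon threshold — 5 grains for
Alnus and Corylus, 15 for Betula. The threshold is attained with `>=`
rather than `>`: "reaching the sum" is the natural reading for integer
counts and remains well defined for fractional concentrations. Start days
are classified into fixed early/moderate/late day-of-year ranges
(see `taxon_config()`); an auxiliary constructor
`season_type_bounds_from_range()` derives three equal periods from an
observed range for new sites, but the bundled reference bounds take
precedence for the three reference taxa.

`season_stats()` reports n, mean, median, sample SD, the coefficient of
variation $100\,\mathrm{SD}/\bar{x}$ (%), range, and a 95% confidence
interval for the mean. The CI uses the $t$ distribution with $n-1$ degrees
of freedom — appropriate at the small $n$ (18–20 years) these records
have, and it reproduces the bundled Krakow reference intervals to better
than 0.1 day for Alnus and Corylus. Day-of-year numbering is true calendar
(January 1 = 1, leap years respected) throughout.

## Training cases and the onset model

Each local minimum detected before a year's season start becomes one
binary case: label 1 if the season started within ten days *after* the
minimum (offsets 1–10), else 0. Two conventions matter:

* The window is the offset set $\{1, \dots, 10\}$; offset 0 cannot occur,
  because a local minimum needs two rising days after it.
* Minima closer than three days to the start (offsets 1–2) are dropped
  from the *training* set: at that range the dip and the onset are not
  usefully distinguishable as cause and signal. The exclusion does **not**
  apply during verification, which scores every considered minimum — the
  bundled 2012 Betula record scores an offset-1 case.

For training, the running-mean series of each year is computed only up to
the season start day; the pipeline pools all minima from the first
computable day of the series. The model is

$$P(\text{onset within 10 days}) =
  \frac{e^{\beta_0 + \beta_d\,\mathrm{Day} + \beta_t\,t_5}}
       {1 + e^{\beta_0 + \beta_d\,\mathrm{Day} + \beta_t\,t_5}},$$

with Day the day-of-year of the minimum and $t_5$ the running-mean
temperature on it. `fit_onset_model()` maximises the Bernoulli likelihood
by Newton–Raphson (equivalently IRLS) with step halving, declaring
convergence when the largest score component drops below $10^{-8}$ or the
parameter change below $10^{-10}$ (at most 100 iterations). The
log-likelihood is evaluated in log-sum-exp form, so linear predictors of
several hundred in magnitude — easily produced by the large negative
Betula intercept at extreme inputs — do not overflow. Perfect separation
is detected (fitted probabilities reaching the labels, or diverging
estimates) and reported as an error rather than returned as a spuriously
"converged" fit; a singular information matrix (e.g. a constant predictor)
likewise errors.

Diagnostics follow standard maximum-likelihood practice: standard errors
from the inverse observed information; both $t$ statistics (with $n-3$
residual df) and Wald $\chi^2$ statistics (df 1), since both conventions
are in common use for this model family; odds ratios $e^\beta$; 95%
coefficient CIs by normal approximation $\beta \pm 1.96\,\mathrm{SE}$,
exponentiated for the odds-ratio scale; and the likelihood-ratio $\chi^2$
against the intercept-only model (df 2) as the goodness-of-fit test. The
decision rule everywhere is strict: forecast YES only when the probability
*exceeds* 0.5, so a probability of exactly 0.5 forecasts NO.

Two interrogation helpers expose the model the way practitioners read it:
`odds_multiplier()` gives the multiplicative odds change for a predictor
shift (e.g. about 2.5× per +5 °C for the Alnus reference set), and
`day_at_probability()` solves $\beta_0 + \beta_d d + \beta_t t_5 =
\mathrm{logit}(p)$ in closed form for the day on which a probability level
is crossed at a fixed temperature — at $t_5 = -4$ °C the bundled Alnus
coefficients cross 0.5 on day 66.

### Bundled reference values

`krakow_coefficients()` loads the coefficient sets fitted to the Krakow
1991–2010 record (from JSON fixtures shipped with the package), and
`krakow_season_starts()` / `krakow_verification_minima()` carry the
observed season starts for 1991–2012 and the 2011–2012 verification
minima. Where the reference record prints slightly inconsistent variants
of the same coefficient (third-decimal differences), the bundled fixtures
use the variant that reproduces the reference worked-example probabilities
at two decimals. One knife-edge case follows from that printing precision:
the 2012 Betula day-82 minimum sits at probability 0.50 to two decimals,
so its YES/NO decision is not determined by three-decimal coefficients;
the tests assert the probability there, not the decision. Similarly, the
tests score the 2012 Corylus day-60 minimum as observed-NO — its offset to
the start (13 days) is outside the ten-day window, which is also the only
scoring consistent with the reference record's own 7-of-9 verification
tally.

## The synthetic-data generator

`simulation_scenario()` fixes a generative process with the structure the
analysis assumes, not a weather model:

* **Temperature.** Daily mean = seasonal sinusoid + AR(1) Gaussian noise,
  from December 20 of the preceding year through April 30. Defaults:
  trough mean −2 °C in mid-January and a 21 °C annual amplitude (matching
  the long-run Krakow figures of about −2 °C in January and 19 °C in
  July), AR(1) coefficient 0.7 and stationary SD 3 °C, which under the
  5-day smoothing yields roughly 2–6 January–March local minima per year
  with dip temperatures spanning about −12 … +6 °C — the ranges seen in
  the reference verification years. The four daily observations are the
  mean plus offsets (+4, −4, −2, +1 °C) with 0.5 °C observation noise,
  re-ordered so the min/max invariants hold.
* **Onset.** Generated through the model's own hazard: minima are
  traversed in day order, each draws a Bernoulli trial at the model
  probability, and the first success places the start uniformly 3–10 days
  later — inside the window, outside the training exclusion. Years where
  no minimum triggers are resimulated (fresh weather draw). Generating
  onset through the fitted form makes parameter recovery a well-posed
  test of exactly the pipeline that is being shipped; it is a calibration
  device, not a phenological claim.
* **Pollen.** Counts are laid down to *invert* the cumulative-sum rule: a
  sub-threshold scatter before the start, the threshold first reached
  exactly on the start day, then a noisy bell-shaped season curve (peak
  120 grains/m³, SD 7 days, clamped at zero). The round trip
  `season_start(simulate_pollen(s)) == s` holds by construction and is
  asserted over a thousand random trials in the tests.

Everything is deterministic given the scenario seed: per-year sub-seeds
are derived arithmetically, so `make_study()` writes byte-identical CSVs
on repeated runs, alongside a `truth.json` recording the coefficients,
per-year minima, trigger days and start days.

What the generator does *not* emulate: real synoptic weather (fronts,
persistence beyond AR(1), snow cover), chilling/dormancy physiology,
pollen transport, or between-taxon correlation. Passing tests on
synthetic data therefore demonstrate that the pipeline's statistics are
correct and calibrated under the stated assumptions — not that the fitted
model is the right phenological model for any particular site.

## What the test suite establishes

The statistical acceptance checks run at these problem sizes, chosen to
keep sampling error well below the tolerances being asserted while the
whole suite completes in about a minute:

* parameter recovery within 3 estimated SEs on 2,000 clean
  model-generated cases, and again on cases induced through the full
  temperature → minima → hazard chain of a 400-year scenario;
* 95% CI coverage between 90% and 98% per coefficient over 200 replicated
  50-year studies (observed ≈ 0.93–0.96);
* likelihood-ratio test size between 0.03 and 0.08 at the 0.05 level over
  500 null replicates of n = 200 (observed ≈ 0.06);
* equivalence of the local-minimum detector with an exhaustive flank scan
  (200 random walks) and of the season-start rule with an exhaustive
  cumulative scan (500 random series);
* exact round-trip of simulated pollen through the season-start rule
  (1,000 trials).

In-sample classification accuracy on the reference study design
(20 years, ~70–80 cases) lands in the low-to-mid 80% range on synthetic
studies, consistent with the reference record; the exact reference
percentages depend on the raw 1991–2010 series, which are not publicly
deposited, so they are checked as properties on synthetic data rather
than reproduced verbatim.

## Known limitations

* The model is site- and taxon-specific by construction; coefficients are
  not transferable without refitting, and the bundled sets describe one
  city's record.
* Only two predictors are used. Rainfall, chilling sums and photoperiod
  are all plausible additions but are out of scope here.
* The 0.5 decision threshold is fixed, matching the reference procedure;
  no ROC-style threshold tuning is provided.
* In-sample classification tables are what the reference procedure
  reports; `holdout_verify()` provides honest out-of-sample verification
  and should be preferred for any new application.
* The E/M/L typing ranges are historical conveniences; observed starts
  can fall outside them, in which case the type is reported as missing
  rather than extrapolated.
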