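---
title: "Methods: nightly HRV trends, fluctuation statistics, and moderated regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nightly HRV trends, fluctuation statistics, and moderated regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvstress)
```

## The scientific problem

Consumer wearables measure nocturnal heart rate variability (HRV) every
night, which makes it possible to ask a within-person question that
pre/post designs cannot: when someone's nightly HRV — or the *day-to-day
fluctuation* of their nightly HRV — trends up or down over a few weeks, does
their self-reported stress, depression, anxiety, or somatisation change in
step? `hrvstress` implements that analysis end to end: inter-beat intervals
to nightly RMSSD, nightly RMSSD to a daily fluctuation statistic, daily
series to five-week trend betas, and trend betas to a moderated
hierarchical regression against questionnaire change scores. Because data
of this kind are personal and rarely shareable, the package also contains a
synthetic-cohort generator with the same statistical structure, so that
every stage is testable and the whole pipeline can be demonstrated without
any participant data.

## From inter-beat intervals to a nightly value

A night is an ordered series of inter-beat intervals (IBIs, ms) with
timestamps. Processing has three stages:

1. **Artifact screening** (`flag_artifacts`). Each IBI is compared with the
   median of its nearest `neighborhood` surrounding IBIs (itself excluded)
   and labelled abnormal when the relative deviation exceeds
   `rel_threshold`. Defaults are `neighborhood = 5` and
   `rel_threshold = 0.30`: a conventional ectopic-beat screening range;
   commercial rings use proprietary constants, so both are exposed as
   parameters. The nearest-5 set of an interior beat is
   \{i−3, i−2, i−1, i+1, i+2\} — at equal index distance the earlier beat is
   preferred, a deterministic tie-break we fixed so that the rule has one
   answer.
2. **Segmentation** (`segment_night`). The night is tiled into contiguous
   half-open 5-minute windows from time zero to the last beat. A partial
   trailing segment participates like any other if it meets the validity
   thresholds below; nothing in the measurement model argues for discarding
   it.
3. **Aggregation** (`nightly_rmssd`). Per segment with a validity fraction
   (normal/total IBIs) of at least `min_valid_fraction = 0.5` *and* at
   least `min_normal_ibis = 30` normal beats, the RMSSD
   $\sqrt{\operatorname{mean}(\Delta \mathrm{IBI}^2)}$ is computed over the
   normal beats; the nightly value is the unweighted mean of the segment
   RMSSDs (weighting by valid-beat count is a defensible alternative; we
   use the unweighted mean and expose the segment values through the count
   fields). `lnRMSSD = log(RMSSD)` is the modelling scale throughout, since
   RMSSD is right-skewed.

Two degenerate cases are decided in favour of missingness rather than
imputation: a night with no valid segment, and a night whose RMSSD is
exactly zero (no successive variation — physiologically implausible, read
as sensor failure; an epsilon-padded logarithm would manufacture an extreme
low outlier). Both yield a missing night.

## The daily fluctuation statistic (HRVsd)

`rolling_sd` computes, for each day $d$, the sample standard deviation
(n−1) of lnRMSSD over the 7 *calendar* days strictly before $d$, defined
only when at least 3 of those 7 days were observed. Choices worth
flagging:

* **"Prior days" excludes the index day.** That is the literal reading of a
  prior-week window; an `include_index` flag provides the inclusive variant
  for sensitivity analysis.
* **Calendar window, not observation window**: an unworn-ring day counts as
  unobserved, it does not stretch the window.
* **SD of lnRMSSD, not a coefficient of variation.** A CV folds part of the
  level into the dispersion statistic; since the analysis studies the
  *interaction* between level trends and dispersion trends, that leakage
  would bias the moderation term. Within-subject analysis does not need the
  between-subject comparability a CV buys.

EMA alcohol items are open from 19:00 to 15:00 the next day (night-shift
schedules); `assign_ema_day` maps a response to the day whose window it
falls in and rejects timestamps in the dead zone. When a window contains
several responses the last supersedes (the participant corrected
themselves).

## Windows, trends, change scores

Questionnaires arrive every 35 days; the daily table is cut into half-open
windows $[q_k, q_{k+1})$ so no day is counted twice. Within a window each
daily variable (lnRMSSD, HRVsd, TST, MVPA, alcohol) is regressed on time —
days since window start — and the OLS slope is the window's *trend beta*;
positive = uptrend. Missing days are omitted; a trend needs at least
`min_trend_obs = 10` non-missing days in the ~35-day window, a guard
against degenerate two-point slopes (the time unit cancels after
standardization, so "per day" is a convention, not a modelling choice).

The 4DSQ's 50 items are recoded 0/1/2 (`no`/`sometimes`/everything above)
and summed into stress (16 items, 0–32), depression (5, 0–10), anxiety
(12, 0–24) and somatisation (16, 0–32). The published item order is part of
the licensed instrument, so the package ships a synthetic default layout
with the correct scale sizes and takes a user-supplied mapping for real
data. A scale with any missing item scores missing — pro-rating would
invent a rule the instrument does not define. Change scores are
later-minus-earlier between consecutive questionnaires. Clinical cut-offs
play no role in the analysis and are not applied.

**Floor screening.** A scale whose scores are ≥ 80% zeros
(`floor_effect_check`, threshold configurable) is refused by the modelling
stage: with essentially no variance, absence of an association is
uninterpretable (a type-II error by construction). The 0.8 default sits
safely below the ~87–93% zero rates at which this pattern is typically
seen in healthy occupational cohorts, while not triggering on mildly
skewed scales.

## The moderated hierarchical regression

All analysed variables — the four change scores and five trend betas — are
standardized at the grand mean over the analysed windows (listwise-complete
windows only). `fit_hierarchical` then fits three nested OLS models for one
outcome $y^*$ (standardized change):

$$
\begin{aligned}
\text{Step 1:}\quad & y^* = \beta_0 + \beta_1\,\mathrm{TST}^* +
\beta_2\,\mathrm{MVPA}^* + \beta_3\,\mathrm{ALC}^* \\
\text{Step 2:}\quad & \ldots + \beta_4\,\mathrm{HRV}^* + \beta_5\,\mathrm{HRVsd}^* \\
\text{Step 3:}\quad & \ldots + \beta_6\,(\mathrm{HRV}^* \times \mathrm{HRVsd}^*)
\end{aligned}
$$

The interaction is the product of the standardized main effects, *not*
re-standardized — standard moderated-regression practice, and the only
convention under which the simple-slope algebra below is exact. Each step
reports the coefficient table, $R^2$, adjusted $R^2$ and the model F;
between steps the fit reports $\Delta R^2$ and two delta-F flavours: the
difference of successive model F statistics (which can legitimately be
negative, since the F statistics test different null models on different
degrees of freedom) and the conventional partial-F test of the added
terms, whose p-value is the one used to compare nested models.

Windows are repeated within participants. The primary fit deliberately
ignores that dependence: in small balanced-ish designs with little
between-subject variance, random-slope mixed models are prone to singular
fits, and OLS on windows is the parsimonious alternative. An optional
cluster-robust covariance (`cluster = "participant_id"`, via `sandwich`)
is available for sensitivity analysis, default off.

**Simple slopes (buffering).** For the step-3 fit, the conditional
coefficient of the HRVsd trend at standardized moderator value $h$ (the
HRV trend) is $\beta_5 + h\,\beta_6$ with variance
$\mathrm{var}(\beta_5) + h^2\,\mathrm{var}(\beta_6) +
2h\,\mathrm{cov}(\beta_5,\beta_6)$, and a t-interval on the residual df.
This is algebraically identical to refitting with the moderator re-centred
at $h$ — the package's tests verify that identity against an actual refit.
A *buffering* pattern is a positive HRVsd coefficient at low HRV trend
that shrinks to nothing as the HRV trend increases.

## The synthetic cohort

The generator's default design: 9 participants observed for 15–55 weeks
(15, 20, 20, 20, 25, 25, 25, 30, 55), questionnaires every 35 days, which
under full adherence yields exactly 47 five-week windows and 56
questionnaires — the analysed sample size this class of study produces.
Nightly lnRMSSD in window $k$ follows

$$ \ln\mathrm{RMSSD}(t) = b_k + a_k t + \varepsilon(t), \qquad
\varepsilon(t) \sim N\!\big(0, \sigma_0 + c_k t\big)_{\ge \sigma_{\min}} $$

with per-window level slopes $a_k \sim N(0, 0.004)$ and dispersion slopes
$c_k \sim N(0, 0.002)$ per day; bases evolve continuously across windows
(each window starts where the previous trend ended). A linear drift in the
noise SD is the simplest mechanism that makes the realized 7-day rolling
SD trend linearly — i.e., exactly the thing the trend-beta stage measures.
Baseline lnRMSSD is $N(4.0, 0.3)$ (RMSSD ≈ 55 ms, a realistic working-age
value); baseline nightly noise is 0.12 on the log scale. Nights are
removed iid at 5.7% and EMA days at 11%, the completeness this study
design typically achieves. TST (minutes), MVPA (minutes ≥ 3 MET) and
Poisson alcohol counts get their own mild per-window trends.

Outcomes are generated on the standardized scale:
$\Delta^* = \gamma^\top(z_{\mathrm{hrv}}, z_{\mathrm{hrvsd}},
z_{\mathrm{hrv}} z_{\mathrm{hrvsd}}, z_{\mathrm{tst}}, z_{\mathrm{mvpa}},
z_{\mathrm{alc}}) + N(0, \sigma_y)$, where the $z$'s are the true latent
slopes standardized by their generating SDs, then discretized by
cumulative rounding within the scale bounds (3 questionnaire points per
standardized unit). The default effects
$\gamma = (-0.1, 0.5, -0.4, 0, -0.2, 0)$ mirror the qualitative pattern of
interest — a clear HRVsd effect, a negative buffering interaction — and
$\sigma_y = 0.8$ puts the full-model $R^2$ near 0.3–0.4, in the range such
designs report. Depression and anxiety are zero-inflated (zero with
probability 0.9, else a small positive count), reproducing the floor
effects that make those scales unmodellable. Scores are additionally
emitted as 50-item response vectors so the questionnaire scorer is
exercised end to end, and `simulate_ibi_night` (default off, for speed)
synthesizes beat-level nights — Gaussian IBIs calibrated to a target RMSSD
plus injected ectopic beats — to exercise the nightly stage.

Two generator modes matter for testing. `simulate_cohort` runs the full
measurement chain, so trend betas are *estimates* and regression
coefficients are attenuated relative to $\gamma$ (measurement error in
regressors biases toward zero) — the right fixture for qualitative
end-to-end checks. `simulate_windows` draws standardized slopes directly
at the window level with no measurement layer — the right fixture for
calibrating the regression engine itself, where recovery should be nearly
unbiased (the only attenuation left is the outcome's own standardization,
a factor $1/\sqrt{1+\sigma_y^{-2}\gamma^\top\Sigma\gamma}$-style shrinkage
of about 2% at the defaults).

### What the generator does and does not emulate

It reproduces the design's *statistical* structure: nesting, missingness
rates, floor effects, trend-driven outcomes. It does not emulate real
physiology — weekly rhythms, autocorrelated stressor exposure, seasonal
drift, or device-specific artifact structure. Passing tests therefore
demonstrate that the pipeline measures what it defines correctly and
recovers effects that exist in data of this shape; they are not evidence
about any real cohort.

## Numerical choices and degenerate inputs

* Trends and regressions use `lm`/`lm.fit` (QR); the test suite checks them
  against closed-form and normal-equations oracles at 1e-8 or better.
* Zero-SD variables abort standardization with the variable named; a
  zero-variance date axis aborts a trend; both indicate a broken upstream
  table rather than something to patch over.
* Missingness is always propagated, never imputed: a short rolling window
  or a sparse trend window yields `NA`, and incomplete windows are dropped
  listwise (and reported) at the modelling stage.
* Determinism: every random stage consumes the R RNG exactly once per
  generated quantity, cohort generation is driven by a single seed, and
  the pipeline driver derives per-stage sub-seeds from the run seed, so a
  config + seed pair reproduces every output file byte for byte.

## Problem sizes in the packaged checks

The packaged tests and the acceptance script run the study-scale design
(9 participants, ≈1,650 person-days, 47 windows) for end-to-end checks;
oracle-equivalence checks use 1,000 random nights of 10–20 minutes and a
1,000-day rolling-SD series; estimator-calibration checks use 100–200
replicates of 500 directly generated windows. These sizes were chosen so
the statistical assertions have sharp expected values while the whole
suite stays interactive.

## Known limitations

* The artifact screen is a reasonable stand-in for proprietary on-device
  algorithms, not a reimplementation of any vendor's.
* Nightly aggregation weights segments equally regardless of their
  valid-beat counts.
* The regression treats windows as independent; the cluster-robust option
  is a patch, not a hierarchical model.
* The synthetic item-to-scale layout cannot score real 4DSQ exports
  without the licensed mapping.
* With ~47 windows, interaction tests are underpowered; simple-slope
  confidence bands at the grid edges are wide and should be read
  qualitatively.
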