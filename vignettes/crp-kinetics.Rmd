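---
title: "Modelling postoperative CRP kinetics and predicting early periprosthetic infection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling postoperative CRP kinetics and predicting early periprosthetic infection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpkin)
```

## The model

C-reactive protein rises after primary hip arthroplasty, peaks around
postoperative day 2–4, and — in the uncomplicated case — resolves along a
stereotyped trajectory. `crpkin` works on the *relative* course: each
patient's postoperative series is aligned so that day 0 is the day of the
maximum and values are fractions of that maximum. Pooled over non-infected
patients, the aligned course is described by a one-phase exponential decay

$$f(x) = \mathrm{span}\cdot e^{-kx} + \mathrm{plateau},$$

with $x$ the days after the peak. The plateau is the fraction of the peak
that does not resolve within the observation window (residual surgical
inflammation at discharge); span + plateau is the model value at the peak
and should be close to 1 after normalization. The cohort-level constants
shipped as `published_decay_model()` are span 0.7235, $k$ = 0.2883/day,
plateau 0.2683 ($R^2$ = 0.716 on the original cohort).

Model assumptions worth keeping in mind:

* a **single** dominant peak: the decay describes the course *after* the
  maximum; second peaks are treated as a separate, discrete warning sign,
  not as part of the curve;
* **exchangeable relative courses**: normalizing by the peak assumes the
  resolution *rate* does not depend on the peak height;
* **one phase**: a two-phase decay adds parameters without materially
  improving fit on this kind of data, and is deliberately out of scope.

## Failure to decline

An infected course fails to resolve. The rule flags a patient when the
observed CRP at $x \in \{3, 4\}$ days after the peak exceeds
$f(x) + 0.15$ of the peak — an additive 15-percentage-point margin, giving
thresholds of 72.30% and 64.67% of the peak under the published constants.
Two conventions matter and are fixed package-wide:

* **The margin is additive** (percentage points of the peak), not
  multiplicative: only $f(x) + 0.15$ reproduces the published thresholds
  and all eight published per-patient predictions.
* **Assessment days are $x = 3$ and $x = 4$ days after the peak.** The
  published prose attaches the labels "day 4" and "day 5" to these
  quantities while its worked per-patient table labels them "(day 3)" and
  "(day 4)"; computing at $x \in \{3,4\}$ reproduces every printed number,
  so the package treats the prose labels as shifted by one day and exposes
  the assessment days as an explicit argument (`ftd_rule()`).

Because blood is drawn only every ~2.4 days, the exact assessment day is
often unsampled. `value_at_day_after_peak()` resolves an observation in a
fixed order: exact day, nearest measurement within ±1 day (earlier wins
ties), linear interpolation between bracketing days, otherwise the day is
unassessable — which is *not* a failure, but is flagged. Exceedance is
strict: a value exactly on the threshold passes. The rule is evaluated
against the cohort-level published model, not per-patient refits: that is
what reproduces the published worked examples, and per-patient fits are
rarely identifiable with 4–8 points.

## Peaks and second peaks

A local peak is a measurement strictly greater than both neighbours
(`min_rise = 0` is the literal rule; a positive `min_rise` suppresses
assay-noise blips, and real data need it). The primary peak is the first
day attaining the maximum; boundary measurements may be the primary peak
but never count as additional local peaks, since an unobserved neighbour
cannot confirm a rise. A *second* peak is any local peak besides the
primary — second in magnitude, not necessarily in time (the published
per-patient table contains a second peak that precedes the primary), and
ties in magnitude resolve to the earlier day.

## Risk scores

Three published predictors are shipped as constants (`linear_score`
objects, also as JSON under `inst/extdata/`), all oriented "score strictly
above cut-off ⇒ infection":

| predictor | features | cut-off |
|---|---|---|
| CRP maximum | `crp_max` | 91.20 mg/L |
| binary logistic score | second peak, CRP max, BMI, sex, CRP-max day, preop mean CRP | −4.725 |
| multinomial score | approach, preop mean CRP, CRP-max day, sex, failure to decline | −8.566 |

The "multinomial" label is kept from the source model; with a binary
outcome it is mathematically a single linear score. Its sex coefficient
(−18.57) is roughly ten times the other terms' scale and makes sex nearly
decisive between codes 1 and 2; it is applied exactly as published and
flagged here rather than "corrected". The multinomial score's
failure-to-decline feature binds to the $x = 4$ assessment day, following
the day-labelling reconciliation above. Coefficients are **not**
re-estimated from data — the original patient-level data are unavailable —
but `fit_logistic()` refits scores on new data by IRLS, with optional
backward elimination by likelihood-ratio tests at a 0.10 stay threshold (a
deliberate simplification of SPSS's "backward conditional" selection).

`roc_analysis()` sweeps thresholds over midpoints of consecutive unique
scores plus ±∞; the trapezoid AUC equals the Mann–Whitney $U/(n_1 n_0)$
form exactly, and the test suite holds the two routes to 1e−12 agreement.

## Group statistics

Per-day comparisons use Welch's *t*-test (the safer default when group
variances differ as strongly as infected vs non-infected CRP does) on each
calendar day with at least two observations per group; sparser days are
excluded from the family and reported. The family is adjusted with the
two-stage Benjamini–Krieger–Yekutieli step-up: stage 1 runs
Benjamini–Hochberg at $\alpha' = \alpha/(1+\alpha)$ to estimate the number
of true nulls $m_0 = m - r_1$, stage 2 re-runs BH at $\alpha' m/m_0$. This
is the canonical two-stage definition (also what common GUI statistics
packages implement); q-values are defined operationally as the smallest
$\alpha$ at which the full procedure rejects, computed by bisection. With
two true effects in a family, the procedure still admits a third (false)
day with probability near $3\alpha'$ ≈ 14% — the test suite checks power
and false-day rarity as separate claims for exactly this reason.

The a-priori sample-size computation inverts the noncentral-*t* power
function of the point-biserial correlation test
($\delta = \rho/\sqrt{1-\rho^2}\cdot\sqrt{n}$, $n-2$ df). The tail count
changes the answer materially (ρ = 0.15, α = 0.05, power 0.95: one-tailed
472, two-tailed 567) and the published planning value corresponds to the
one-tailed test, so `power_spec()` takes `tails` explicitly rather than
defaulting silently.

## The synthetic cohort generator

No patient-level data are deposited, so `generate_cohort()` simulates
cohorts with the statistical structure the analysis assumes. Per patient it
draws covariates (age ~ N(71.18, 11.92) truncated to adults; BMI
~ N(27.08, 5.40); sex P(male) 0.4486 / 0.875 by infection group; approach
codes with the cohort's observed frequencies; hospital stay
N(10.30, 4.25) / N(25.86, 20.95) truncated ≥ 4 days), then builds a latent
trajectory — preoperative baseline, linear rise from surgery to the peak
day, `peak · f(x)` decay after it — and samples it at whole days spaced by
N(2.43, 0.92) draws clipped to ≥ 1 day, starting on day 1 or 2, until
discharge, with one preoperative sample at day −1. Multiplicative
log-normal noise (CV 0.15 by default) and a 0.5 mg/L assay floor are
applied last. Infected patients additionally receive, with probability
0.5, a triangular second-peak bump (day ~ N(8.25, 3.20) truncated past the
peak, amplitude 0.5–0.9 of the peak, width 3–5 days) and a late-elevation
multiplier (×1.8 from day 10) that reproduces the late separation between
infected and non-infected courses.

Choices made where the defaults were genuinely open, and their rationale:

* **Log-normal CRP quantities**, moment-matched to the target mean/SD: CRP
  is positive and right-skewed, with SD of the same order as the mean.
* **Peak-day weights (0.25, 0.50, 0.25) on days {2, 3, 4}** — mode at day 3,
  matching the known day-3 peak of post-arthroplasty CRP.
* **Approach weights renormalized**: the published cohort frequencies sum
  to 96.7% (rounding in the source table), so the generator rescales them
  to a proper distribution.
* **The sampling schedule is shifted to include the peak day** (the nearest
  scheduled draw moves onto it, keeping the draw count and the ~2.43-day
  mean interval). Routine early postoperative panels are near-daily, so the
  peak is essentially always observed; analytically this makes the sampled
  maximum equal the latent peak, so a noiseless, infection-free cohort
  aligns exactly onto $f(x)$ for $x > 0$ — the generator's self-consistency
  property.
* **Late-elevation factor 1.8** is a free parameter, not an estimate from
  any dataset.

What the generator does *not* emulate: measurement dropout after revision
surgery, WBC/haemoglobin/platelet panels, approach-specific CRP
differences, and any correlation between covariates and CRP kinetics
beyond the infection label. Passing tests on generated cohorts therefore
demonstrate the pipeline's internal correctness and calibration under the
stated structure — not clinical performance on real patients, which only a
prospective cohort can show.

`generate_worked_fixture()` is a deterministic eight-patient cohort whose
peak days/values, single listed second peak, and observed assessment-day
CRPs equal the published per-patient table; every in-between sample and all
covariates are synthetic constructions chosen so peak detection and the
failure-to-decline rule resolve to the published flags.

## Numerical choices

* The decay fit (`fit_one_phase_decay()`) uses Levenberg–Marquardt least
  squares from the fixed start (0.7, 0.3, 0.25), relative tolerance 1e−10,
  at most 500 iterations — deterministic by construction. A fitted $k \le 0$
  or constant input raises "no decay"; fewer than 3 distinct $x$ values is
  an error.
* Ties for the primary peak resolve to the first (earliest) day.
* Patients whose peak is their final sample contribute only the point
  (0, 1) to a pooled fit; they carry no information about the decay but do
  no harm.
* Problem sizes in the test suite: parameter recovery uses 200 patients ×
  21 aligned days over 20 seeds; the FDR oracle comparison uses 10,000
  random p-vectors of length ≤ 20; ROC dual-route equivalence uses 1,000
  random score sets; cohort-moment checks pool 50 seeds × 200 patients.

## Known limitations

* The published coefficients are reproduced, not re-derived: the original
  708-patient dataset is unavailable, so cohort-level empirical results
  (AUCs, sensitivities, the Fig.-level q-values) cannot be replicated and
  are not claimed by any test.
* With ~1% prevalence, a realistic simulated cohort contains too few events
  to refit a six-feature logistic model stably; the workflow's refit step
  reports whatever the data support (often after heavy elimination) rather
  than pretending otherwise.
* The failure-to-decline rule inherits the sampling grid: with draws every
  ~2.4 days and a ±1-day tolerance, some patients are unassessable at a
  given day; they are flagged, not imputed.
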