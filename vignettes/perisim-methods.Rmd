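---
title: "Methods: simulating critical times for perimetric variability and reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating critical times for perimetric variability and reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisim)
```

## The question

A patient's visual-field (VF) test results fluctuate between visits even
when nothing has truly changed, and some results are lost outright
(unreliable tests that must be discarded). Both phenomena have a stable,
subject-specific core: an *intrinsic variability* — the test–retest noise
SD of the mean deviation (MD) index, in dB — and an *intrinsic
reliability* — the probability that any given test yields usable data.
Neither is directly observable; a clinician can only watch running
estimates evolve as tests accumulate. `perisim` simulates that process
and asks: **after how much follow-up do the running estimates
stabilize?** We call that the *critical time*.

## The generative model

Each simulated subject carries a ground-truth quadruple, sampled
independently:

| parameter | distribution | default | units |
|---|---|---|---|
| baseline MD, $MD_0$ | Normal | mean $-4$, SD $2$ | dB |
| progression rate, $r$ | Azzalini skew-normal | location $-0.05$, scale $0.8$, shape $-2$ | dB/year |
| intrinsic variability, $\sigma$ | lognormal | $\exp(N(0.5, 0.4))$ | dB |
| intrinsic reliability, $p$ | scaled beta | $0.5 + 0.49\,\mathrm{Beta}(9, 1.5)$ | — |

The defaults describe a mostly early-glaucoma population with a long
tail of fast progressors, mostly-high reliability with a left tail of
poorly reliable subjects, and a variability median of
$\exp(0.5) \approx 1.65$ dB. The skew-normal is sampled by the
two-normal delta representation
($X = \xi + \omega(\delta|Z_0| + \sqrt{1-\delta^2} Z_1)$,
$\delta = \alpha/\sqrt{1+\alpha^2}$), which is exact and needs no
rejection step. The lognormal parameters are those of the underlying
normal on the log scale; the beta low/high bounds are a linear rescaling
of a standard Beta(9, 1.5).

A test at visit time $t$ returns
$MD = MD_0 + r\,t + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$,
and is independently usable with probability $p$. Discarded tests still
count as administered. Two schedules are built in:

* **long-term**: 81 visits, 3-monthly over 20 years (times in years);
* **short-term**: 28 daily visits (times in days; progression enters as
  $r\,t/365$, so its negligibility over 28 days is a property of the
  data, while *ignoring* it is an analysis choice).

Four tests per visit form the **core** series; the 12 study conditions
(1–4 tests/visit × 1-, 2-, or 4-fold review interval) are derived by
*subsetting* the core, never by re-simulation, so a sparser condition's
data are exactly nested in a denser one's.

```{r model-demo}
set.seed(1)
pop <- sample_population(500)
summarize_population(pop)
```

## Running estimates

At each visit of a derived condition we form, per subject:

* **Reliability estimate**: cumulative usable tests / cumulative
  administered tests.
* **Variability estimate**: the sample SD ($n-1$ denominator) of all
  valid MD values so far. For the long-term schedule the values are
  first *normalized*: an ordinary-least-squares slope is fitted to all
  valid $(t, MD)$ pairs up to the current visit and **all** values are
  re-adjusted as $MD - \hat r\,t$ before the SD is taken (the clinical
  reality that the true progression rate is unknowable). The estimate is
  undefined until two valid values — and, long-term, valid data at two
  distinct visit times — exist. Short-term series use raw values.

The cohort engine computes all of this from running sums
($N, \Sigma t, \Sigma y, \Sigma t^2, \Sigma y^2, \Sigma ty$), giving the
OLS slope and the adjusted-value SD in closed form per visit, vectorized
over subjects; `running_slope_and_adjust()` is the transparent
single-series implementation of the same definitions, and the test suite
checks the two routes against each other.

## Rolling windows and critical times

Scanning the per-visit estimates in order:

* **TcV / TcR** (clinically observable): the time of the third visit of
  the first three *consecutive* estimates within tolerance of each
  other. "Within 5%" is operationalized as
  $\max - \min \le \tau \cdot \text{mean}$ over the triplet
  ($\tau = 0.05$ by default); a triplet of identical values, including
  zeros, qualifies.
* **TgV / TgR** (validation-only): the third visit of the first run of
  three consecutive estimates each within $\tau \cdot \text{truth}$ of
  the subject's true $\sigma$ or $p$.

Visits at which no valid result was obtained — and visits whose estimate
is not yet defined — are *skipped without resetting* the window. The
skip rule is applied to both windows: without it, a subject losing data
would accrue qualifying triplets of literally unchanged estimates, which
rewards unreliability. An in-band/out-of-band decision only resets the
ground-truth run when the visit actually carried an estimate. Subjects
whose criterion is never met within the schedule horizon are **censored**:
they are excluded from medians/IQRs and count in the denominators of
cumulative detection curves. Critical times live on the visit grid; we
do not interpolate.

```{r window-demo}
find_critical_time_consecutive(0:4, c(1.00, NA, 1.02, NA, 1.01))
```

## Tunable parameters that matter

* `tolerance` (proportion, default 0.05; 0.10 as a laxer variant): the
  window tolerance. Qualification is monotone in it — raising it never
  delays a critical time (a property test asserts this).
* `tests_per_visit` (1–4) and `interval_multiplier` (1, 2, 4): the
  testing intensity; more tests and tighter review shorten variability
  critical times. Reliability critical times behave differently: with
  one test per visit the early reliability estimate is extremely coarse
  (often exactly 1), so triplets agree *sooner* than with four tests per
  visit, where finer granularity exposes real fluctuation — TcR can
  lengthen as tests are added.
* `n_subjects` (default 100 000) and `seed`: a single RNG stream with a
  fixed, documented draw order (population first, then noise, then
  usability flags) makes every artifact bit-reproducible for a given
  configuration and seed. We use one stream rather than per-subject
  substreams because derived conditions are subsets of the core — there
  is no second simulation that would need stream alignment.

## Design choices where the design was open

* **Triplet rule denominator.** "Within 5% of each other" admits several
  readings (each pair within 5%, range relative to the first value,
  range relative to the mean). We fixed range ≤ τ·mean and kept it; the
  floor behavior (a triplet of equal estimates qualifies at the third
  eligible visit) is the part the reliability results are sensitive to,
  and it is shared by all three readings.
* **Re-adjust all vs adjust once.** Normalizing *all* accumulated values
  with the current slope estimate follows from computing the SD over
  "all adjusted values so far"; the alternative (freezing each visit's
  adjustment at the slope estimated when it was current) was
  implemented and compared during development and changed the
  consecutive-criterion medians by at most one visit while degrading
  ground-truth agreement, so the re-adjust-all definition stayed.
* **Per-test reliability.** Usability is an independent Bernoulli per
  test, not per visit: a 4-test visit can lose 0–4 tests.
* **Independence of parameters.** No correlation between $MD_0$,
  $\sigma$ and $p$ is modeled. A consequence worth stating: the
  consecutive-window criterion is exactly invariant to offsets and to
  rescaling of the noise, so under this generator the long-term TcV is
  *distributionally independent* of $MD_0$, $r$ and $\sigma$ — baseline
  parameters can only influence critical times through reliability-driven
  data loss. Regressions of TcV on the other baseline parameters
  therefore estimate null coefficients whose fitted signs are sampling
  noise.

## Numerical notes

* Sums of squares are clamped at zero before the square root
  (cancellation guard); the adjusted-SD closed form is algebraically the
  residual SD about the running fit.
* Quantiles everywhere are type 7 (linear interpolation between order
  statistics); printed medians are visit-grid-quantized so the rule
  rarely matters.
* Degenerate inputs: a constant outcome regresses to coefficient 0 and
  $R^2 = 0$; a zero-variance predictor is flagged, not fitted; an
  all-zero estimate triplet qualifies (0 ≤ τ·0); a subject with no
  usable data is censored everywhere.

## What the generator does and does not emulate

It emulates stable subject-specific noise and data-loss rates, linear
true progression, and schedule intensity. It does **not** emulate
learning or fatigue effects, aging decline distinct from progression,
floor effects at advanced damage, pointwise (24-2 location-level)
structure, intra- vs inter-visit variance components, or any coupling
between disease severity and variability. Passing tests therefore show
that the estimation and windowing machinery is correct under the stated
model — not that real perimetric series stabilize on these timescales.
In particular, the absolute scale of variability critical times is
sensitive to the window operationalization in ways the reliability
floors are not, and with cumulative-SD estimates a 5% triplet band is a
demanding requirement: typical variability stabilization takes roughly
a dozen informative visits per condition in this implementation.

## Problem sizes

The test suite samples 100 000 parameter quadruples for
distribution-recovery checks and simulates cohorts of 20 000 subjects
for cohort-level checks (floor medians are visit-grid-quantized and
already exact at that size; ordering properties are asserted there too).
The orchestrated default, `default_run_config()`, keeps the full
100 000-subject study conditions.
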