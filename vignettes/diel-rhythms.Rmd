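---
title: "Detecting diel rhythms in benthic count series: models and design choices"
author: "BenthicRhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diel rhythms in benthic count series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BenthicRhythms)
```

## The problem

Counts of megafauna in repeated seafloor video transects are a proxy for
population activity: an animal moving more is more likely to cross the
camera's field of view during a sampling window. A typical campaign
yields, per taxon and month, 30 observations — five days at a 4-hour
cadence — next to hourly sensor records of flow, temperature, oxygen,
chlorophyll and density. At ~900 m depth there is no light cycle;
day/night structure reaches the benthos through periodic hydrodynamics
and chemistry. The package asks three questions of such data: is there a
~24-h rhythm in the counts; which environmental variable co-varies with
it, at what delay; and at what time of day does activity peak.

This vignette records the models, their assumptions, and every numerical
choice a maintainer would want to know about. All time handling is local
Pacific Standard Time, fixed UTC−8 with no daylight saving; timestamps
label the **start** of a sampling window.

## From raw records to regular series

**Pairing and normalization.** Each 4-h slot holds two transect legs
(out and back). Counts are summed over the pair and normalized by usable
footage: `value = sum(counts) × 10 / sum(usable_minutes)`, giving
individuals per 10 min. Slots are anchored at local midnight, which
yields the canonical six time-of-day bins; a record belongs to the slot
containing its timestamp. If per-leg durations are unknown, a nominal
pair duration (default 20 min) is used; a slot with a single usable leg
is normalized by that leg's footage (with a warning) or dropped, as
configured; a slot with zero usable minutes is missing.

**Zero filter.** A series with zeros in strictly more than 1/3 of its
observations is discarded: with 30 points, period estimates from
zero-inflated series are unstable. The boundary is read strictly —
exactly 10 zeros in 30 observations is kept.

**Environmental binning.** Sensor streams are averaged into clock-hour
bins; empty hours stay missing. Flow is handled as vectors: N–S and E–W
components are binned, then transformed to magnitude `√(ns² + ew²)` and
direction `atan2(ew, ns)` in degrees clockwise from North — the heading
the flow moves *toward* (ADCP practice; the convention is stated here
because plausible alternatives abound). Direction is circular: all
averaging uses the unit-vector mean (350° and 10° average to 0°), and an
hour whose resultant vanishes (antipodal directions) is flagged
undefined rather than silently averaged. Hourly series are further
averaged onto the 4-h biological grid (at least one non-missing hour per
slot) for cross-correlation and ordination, and z-scored — sample
(n−1) standard deviation, as everywhere in the package — before entering
the RDA.

Missing biological slots are kept as missing; model fits and
correlations drop them pairwise while the surviving observations retain
their calendar index. No imputation is done.

## The rhythm model

Counts are modeled as a single sinusoid in the slot index `t = 1..n`
(4-h steps):

```
y(t) = a1 cos(2πt/a4) + a2 sin(2πt/a4) + a3 [+ a5 t]
```

with period `a4` estimated in steps and reported in hours (×4),
amplitude `√(a1² + a2²)`, and acrophase the clock time of the fitted
maximum. The optional linear term `a5 t` absorbs a low-frequency drift
(a spring-tide signal rides under some series); it is off by default and
enabled per taxon.

Numerical choices:

* **Optimizer.** Levenberg–Marquardt (`minpack.lm::nlsLM`) with box
  bounds on the period and up to 200 iterations; standard errors,
  t-statistics and two-sided p-values from the Jacobian covariance at
  the optimum on `n − k` degrees of freedom (`k` = 4 or 5).
* **Initialization.** `a4` starts at 24 h (the diel hypothesis);
  `a1, a2, a3` come from closed-form harmonic regression at that period;
  with the trend model, `a5` starts at the slope of a linear pre-fit and
  the harmonic start is computed on the detrended series.
* **Period band.** `a4` is constrained to 16–32 h (configurable). The
  band keeps the optimizer on the diel branch and away from the
  semidiurnal tidal harmonic at ~12.42 h, which a free period on 30
  noisy points will otherwise sometimes lock onto. A fit pinned at a
  band edge raises a warning.
* **Degenerate inputs.** If the starting values already fit exactly
  (noiseless data at the initial period) the gradient there is singular
  and the optimizer cannot move; the start is returned as the optimum
  with zero standard errors. For a constant series the amplitude is 0
  and the period is unidentifiable: its p-value is `NA`, not a number.
  Any other optimizer failure returns a result flagged
  `converged = FALSE` carrying diagnostics, never an exception.
* **Acrophase convention.** The slot index maps to clock time at the
  **midpoint** of the 4-h window (counts accrue over the footage; the
  midpoint is the one-point quadrature of the window). The synthetic
  generator evaluates its rate the same way, so acrophases round-trip.

**Caveat on the period p-value.** Significance of the period is the Wald
test `t = a4/se(a4)` — the convention under which published
period-coefficient p-values of this kind are reported. It measures how
precisely the period is identified, *not* whether a rhythm exists: `a4`
is bounded away from zero, so even noise yields a small p when the
optimizer settles anywhere in the band with moderate curvature. Rhythm
presence should be judged by the amplitude, the waveform, and the
periodogram of the driving variables together, not by this p-value
alone. Least-squares p-values here also ignore residual autocorrelation;
with n = 30 and a fitted period of ~6 steps this is a real, documented
approximation.

## Periodograms

Hourly environmental series get the classic Lomb–Scargle treatment:
mean-subtracted, variance-normalized power with the per-frequency time
offset τ that makes the cosine and sine regressors orthogonal — so the
power at every frequency equals the least-squares sinusoid-fit statistic
there, a property the tests assert to 1e−8. Missing hours are simply
absent; the statistic is exact under uneven sampling.

* **Band and resolution.** Default period band 2–48 h with oversampling
  `ofac = 8`: frequency step `1/(span × ofac)`, about 0.5 h of period
  resolution near 24 h for a 5-day record and ~0.2 h for a 14-day one.
  The band is clipped to (2 × sampling interval, series span) with a
  warning.
* **Significance.** Peak false-alarm probability
  `p = 1 − (1 − e^{−z})^{n_eff}` with `n_eff` from the Horne–Baliunas
  approximation `−6.362 + 1.193 n + 0.00098 n²`; the α = 0.05 threshold
  is that formula inverted. Horne–Baliunas is approximate: for strictly
  even complete sampling it overcounts independent frequencies and the
  peak p is conservative; under moderate random gaps (the regime the
  statistic serves) the package's null simulations show the nominal 5%
  rate is matched closely. No multiple-testing correction is applied
  across variables — peaks are reported per variable.
* **Ties.** Exactly tied maxima resolve to the longer period, with a
  warning.
* A constant series returns all-zero power with a warning rather than
  dividing by a zero variance.

## Coupling: cross-correlation and lagged RDA

The sample CCF uses the fixed-mean, divisor-`n` convention —
`ccf(k) = Σ(x_t − x̄)(y_{t+k} − ȳ)/(n s_x s_y)` — under which the
white-noise band is ±z_{1−α/2}/√n (0.36 at n = 30, α = 0.05; the α = 0.10
band 1.65/√n ≈ 0.30 is also reported, since weaker responses can be
significant only there). Only non-negative lags are computed, environment
leading: abundances do not drive the ocean. Lags are multiples of the
4-h grid, by default up to 24 h.

For the multivariate view, the biological matrix is lagged 12 h behind
the environment (the delay the cross-correlations identify; the spec of
the lag is a config key), aligned, and regressed on the z-scored 4-h
environmental averages; the fitted values are eigendecomposed (PCA of
the constrained variation). Conventions:

* Responses are centered, not scaled — abundances share units.
* Flow **direction** is excluded from the predictor set: it is circular,
  and a linear RDA term in degrees is meaningless. Magnitude,
  temperature, oxygen, chlorophyll and density enter.
* Scores follow the correlation-biplot (scaling 2) convention: predictor
  biplot scores are correlations of each predictor with each axis's site
  scores (range −1 to 1); species scores are response eigenvectors
  weighted by √eigenvalue; site scores are standardized.
* Eigenvector signs are arbitrary, so axes are canonicalized: the
  predictor with the largest absolute loading is made positive on each
  axis, which makes score tables reproducible run to run.
* Collinear predictors are dropped with a warning (QR rank); a
  rank-deficient response proceeds on its reduced rank.

## Waveforms, MESOR and phase

Each series is averaged by clock bin across its days — six 4-h bins for
biology, twenty-four 1-h bins for environment — with per-bin sample
standard deviations. The MESOR (Midline Estimated Statistic Of Rhythm)
is the unweighted mean of the bin means, asserted in the tests as an
exact identity; bins strictly above it form the peak. An empty bin is
missing and excluded from the MESOR with a warning.

Phase classification compares peak bins with a night window (defaults:
summer 21:30–05:30, winter 16:45–08:00 local, approximating the
photoperiod at the study latitude; fully configurable). A bin containing
a sunrise/sunset transition strictly in its interior is crepuscular;
otherwise bins fully in day are diurnal, fully in night nocturnal, a
mixture "mixed". **Which bins are classified is a genuine design
choice**: for any sinusoidal rhythm the above-MESOR set spans half the
cycle, so classifying *all* peak bins would brand every sinusoid
crepuscular — the dawn-side shoulder bin is above the midline almost
surely. The package therefore classifies the *dominant* peak (the bin or
tied bins at the waveform maximum), which carries the acrophase; the
literal all-peak-bins rule remains available via `on = "above-mesor"`.

A robustness check recomputes the waveform with each bin's single
maximum observation removed; a peak that survives is not the artifact of
one lucky transect.

## What the generator emulates — and what it does not

`genStudy()` produces, per campaign month: hourly environmental tables
(flow N–S/E–W components from a magnitude-plus-heading model,
temperature, oxygen, chlorophyll, density), each a baseline plus
sinusoidal components (diel 24 h and/or tidal 12.42 h) plus Gaussian
noise; and transect-leg tables whose counts are Poisson draws. The rate
is the rectified sinusoid
`max(0, mesor + A cos(2π(t − acrophase)/period) + trend·step +
gain·driver(t − lag))` evaluated at the slot midpoint, each 10-min leg
contributing `Poisson(rate × minutes/10)` counts. Choices worth
restating:

* **Poisson noise** is a modeling choice — visual counts are naturally
  Poisson-like — and the two legs of a pair are independent Poisson
  draws; the published record is silent on both, and the manifest flags
  them as generator choices.
* **Rectification at zero** (not a log link) keeps the amplitude in
  count units, matching the additive fitted model.
* **Coupling is linear in the lagged raw driver** (default lag 12 h).
  A negative gain shifts the baseline down by `|gain| × driver baseline`;
  the default crab-like taxon compensates with a higher intrinsic mesor
  so its *effective* midline stays realistic.
* The default three-taxon community (diurnal swimmer with ascending
  trend coupled to flow; crepuscular dawn taxon coupled to chlorophyll;
  nocturnal taxon coupled to oxygen) is sized so all three pass the
  zero filter — it emulates the *retained* community a campaign would
  analyze, with mean abundances of order 3–7 ind/10 min.
* One master seed drives everything; per-month and per-taxon substreams
  are derived arithmetically, so bundles are byte-identical across runs.

What it does **not** emulate: animal movement or spatial structure
(counts are i.i.d. given the rate — no overdispersion, no serial
dependence beyond the rate), visibility dropouts correlated with storms,
tidal constituents beyond user-specified sinusoids, or lunar cycles
beyond the linear trend. Passing tests on synthetic data therefore show
the estimators recover the *assumed* generating structure; they cannot
show the structure is right for any particular real dataset.

## Test and simulation sizes

The test-suite Monte-Carlos use the study's own dimensions — 30-slot
count series, 120-sample hourly series — with 50–200 replicates per
property (500 for the CCF null band), sizes at which the asserted rates
have comfortable binomial margins. Null-calibration simulations draw
white noise at 120 random hourly slots of a ~7-day record: an uneven
sampling pattern (a quarter of hours lost, as sensor outages produce)
under which the Horne–Baliunas count is near-exact; for complete even
records the same threshold is mildly conservative, as noted above.
Monte-Carlos use one seeded RNG stream per experiment rather than
per-iteration reseeding.

## Known limitations

* Wald p-values for the period ignore residual autocorrelation and do
  not test rhythm presence (see the caveat above).
* The Horne–Baliunas `n_eff` is an approximation; no Baluev bound or
  bootstrap null is provided.
* RDA axis significance is not tested (no permutation test), matching
  the analysis the package mirrors; circular–linear association for flow
  direction is out of scope.
* The zero filter, nominal durations and night windows are configurable
  but their defaults encode one study design; other deployments should
  set them deliberately.
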