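---
title: "Methods: diel displacement, movement predictability, and their mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diel displacement, movement predictability, and their mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the two movement descriptors, the models that relate them to forage and
social rank, the synthetic generator used in place of unavailable field
data, and the numerical choices made where the methods literature leaves
the design open.

## The two movement descriptors

**Diel displacement (DD).** GPS collars on free-ranging savannah
elephants record one fix per hour. The hourly net displacement
$S^N_t$ is the great-circle distance between successive hourly
positions, computed with the haversine formula on a sphere of radius
6371 km (the haversine form is stable for the short steps involved;
"great-circle distance" alone does not pin down a formula, so the
choice is documented here). DD for a day is the sum of its 24 hourly
displacements and is a proxy for daily energy expenditure.

Failed fixes are filled by linear interpolation of latitude and
longitude, independently and in raw degrees, between the temporally
nearest successful fixes. Interpolating in degrees rather than along
the great circle is an approximation; at hourly step sizes (typically
well under 5 km) the discrepancy is far below measurement noise. A day
is *valid* when at least 20 of its 24 hourly fixes succeeded; the gap
length interpolated across is otherwise unlimited, because the 20-fix
rule alone governs validity. Invalid days are retained, flagged, and
excluded from modelling.

Two boundary conventions are configurable but have sensible defaults
for an East African study area: days are bounded at local midnight
taken as UTC+3, and the displacement of hour $t$ belongs to the day
containing the *start* of the hour, so each day owns exactly 24 hourly
displacements and its last one reaches into the following day's first
fix. Whether the original analyses used UTC or local days is not
documented anywhere we could verify; UTC+3 is the defensible choice
for Kenya and the offset is a parameter (`day_offset_hours`).

**Movement predictability (MP).** Elephants switch movement modes
within a day; when that switching follows a circadian routine, the
hourly displacement series is strongly autocorrelated at 1-3
cycles/day. MP for a day is the proportion of its 24 hours whose
wavelet power at any of the periods 24, 12 or 8 h significantly
exceeds a white-noise null. In practice MP is usually near 0 or near
1: a day either shows circadian structure or does not.

The spectral machinery, in order:

* *Per-day normalization.* Within each complete day the series is
  min-max rescaled to $[0, 1]$ (a constant day maps to zeros). This
  removes day-to-day variance changes so the statistic responds to
  periodicity, not amplitude; it also makes MP exactly invariant to
  rescaling the raw displacements.
* *Wavelet transform.* Continuous Morlet transform (centre frequency
  $\omega_0 = 6$, the standard choice in circadian and movement
  ecology) of the concatenated multi-day normalized series per
  individual — not day by day, so that multi-day periodicity is
  resolved. Implemented by FFT convolution with the analytic Morlet
  daughter wavelets, mean-removed and zero-padded to twice the next
  power of two; the tests verify agreement with a direct time-domain
  convolution to a relative 1e-6. Scales are indexed by Fourier
  period; the full display grid spans 2-48 h at 12 voices per octave,
  while classification needs only the 24, 12 and 8 h scales.
* *Significance.* The null is Gaussian white noise with variance equal
  to the variance of the analyzed (normalized) series of that
  individual. 1000 surrogate series of matched length are transformed
  and the pointwise $(1-\alpha)$ quantile of power per scale — pooled
  over surrogates and over time steps outside that scale's e-folding
  cone of influence — is the threshold, with $\alpha = 0.05$ and no
  correction across the three scales: the "significant at any of 1, 2
  or 3 cycles/day" union rule is the definition. Because the
  transform is linear and the null Gaussian, thresholds scale exactly
  in proportion to the null variance; the pipeline therefore draws one
  unit-variance set of surrogates per series length and rescales per
  individual (`scale_null()`), which is an exact identity, not an
  approximation.
* *Edge handling.* Days whose hours fall inside the 24-h cone of
  influence are flagged `edge` but kept — trimming them would discard
  real data, and the flag lets an analyst check sensitivity.

A Fourier view (`fourier_spectrum()`) complements the wavelet one: a
mean-removed periodogram with a 10% Tukey cosine-bell taper and a
modified Daniell smoother with spans (3, 3), normalized by the series
variance so white noise sits at power 1. The taper fraction and spans
are conventional defaults; the methods they implement are named in the
source literature but their parameters are not.

## Forage availability

A single daily ecosystem NDVI series stands in for forage conditions.
Records are assigned the NDVI of their date (linear interpolation in
time when the series is coarser than daily; days outside the series
span are dropped with a warning). Days are classified into low, medium
and high forage availability (LFA/MFA/HFA) by three *equal-width* bins
over the NDVI range observed across all valid movement days, pooled
over individuals; intervals are half-open with a closed top so the
partition is exhaustive.

## The mixed models

For response $n_{i,j}$ of individual $j$ on day $i$ (DD in km, or MP
as a proportion):

$$ g(E[n_{i,j}]) = \beta_0 + \beta_1\,\mathrm{NDVI}_i + \text{rank}_j
   + \mathrm{NDVI}_i{:}\text{rank}_j + \phi_1 n_{i-1,j} + \phi_2 n_{i-2,j}
   + b_j $$

with $b_j \sim N(0, \sigma_b^2)$ random intercepts, rank a
four-level factor (low, medium, variable, high; reference "low") and
no random slopes. Only days forming triplets of three consecutive
valid days enter, so both lags are observed. $g$ is the identity for
DD (a linear mixed model, fit by plain maximum likelihood so that
likelihood-ratio tests on fixed effects are valid) and the logit for
MP.

The MP likelihood needs a decision: the original modelling fit a
logit-link mixed model to a proportion, without recording whether the
response was a quasi-likelihood proportion or a binomial count. We
model $24 \times \mathrm{MP}$ as binomial with 24 trials (Laplace
approximation via `lme4::glmer`), which matches the logit link, the
$[0,1]$ support, and the hour-counting construction of MP exactly; lag
covariates stay on the proportion scale (the other contender, the
logit scale, is undefined at MP of exactly 0 or 1, which dominates real
data). NDVI enters unstandardized on its native $[0,1]$ scale.

Inference helpers mirror the reported analyses: `lrt()` for nested
likelihood-ratio tests ( `lrt_ladder()` reproduces the full-vs-null,
interaction, and two lag comparisons), `rank_slopes()` adds the
interaction coefficients to the NDVI slope per rank,
`slope_percent_change()` contrasts high vs low rank to the nearest
percent, and `predict_response()` draws population-level curves with
lags held at their across-individual median (DD) or mean (MP).

## The synthetic generator

No public elephant tracking archive accompanies the original study, so
the generator is a first-class module: it produces hourly tracks, an
NDVI series and a rank table whose statistical structure is the one
the analysis assumes, with exported ground truth.

* **NDVI**: two rainy seasons per year (a twice-yearly cosine peaking
  around May 1 and late October) plus AR(1) noise (coefficient 0.97,
  innovation SD 0.015), clipped to $[0.05, 0.9]$. Base 0.40 and
  amplitude 0.25 give a dry-season floor near 0.15 and wet-season
  flushes near 0.65, a realistic span for a semi-arid East African
  ecosystem and wide enough that each equal-width forage bin receives
  a nontrivial share of days.
* **Daily responses**: generated from exactly the mixed-model
  structure above, with the reference coefficient estimates as the
  default ground truth. The DD recursion runs on observed values,
  floored at 0.1 km (daily travel cannot be negative); MP days realize
  binomial(24)/24 proportions; both recursions start at their
  stationary means. Defaults: random-intercept SD 0.15 (DD) and 0.2
  (MP), DD residual SD 0.8 km — chosen so the generated DD coefficient
  of variation (about 0.4) matches the CV range real elephants show,
  not fit to any test outcome.
* **Tracks**: each day draws 24 hourly step lengths — a fixed diurnal
  template mixing 1, 2 and 3 cycles/day harmonics (with mild
  lognormal noise) on "periodic" days, exchangeable lognormal steps
  otherwise — rescaled to sum exactly to the day's DD and laid out
  with independent uniform headings around (0.55° N, 37.5° E). The
  per-day periodic state is Bernoulli with probability equal to the
  day's MP. Headings without persistence and a fixed-latitude degree
  conversion are simplifications (no home-range geometry, rivers or
  settlements); they cost under 0.05% in round-trip DD accuracy.
  Fixes fail independently at rate 0.05 by default.
* **Rank assignment**: 3 high, 2 medium, 3 low, 1 variable-ranked
  individual, 900 days each — the scale of the multi-year study the
  package is designed around. ("Variable" is a real level: a
  matriarch died mid-study in the source population, so her family's
  rank was not constant.)

What the generator does *not* emulate — spatially heterogeneous
forage, directional persistence, migration excursions, temporally
clustered fix failures — bounds what passing tests can show: they
validate the estimators and the pipeline plumbing under the stated
model, not robustness to every field pathology.

## Numerical choices and degenerate inputs

* Constant displacement series have no spectral structure: MP is 0 by
  definition (the white-noise null is undefined at zero variance and
  `bootstrap_thresholds()` refuses it).
* Interior forage-bin edges belong to the interval they open; the
  range maximum belongs to HFA.
* Mixed models: `lme4` defaults with ML (not REML); non-convergence is
  flagged on the returned object, never silently replaced; rank-deficient
  fixed-effect designs error naming the collinear columns; LRT
  statistics are clipped at zero.
* Loess trends use degree-1 local regression with the exact "direct"
  surface (span 0.75 by default); the CV-vs-NDVI trend uses a sliding
  window of the span-nearest neighbours for SD/mean, then smooths
  those points, skipping zero-mean windows.
* Wavelet thresholds pool the quantile over surrogates x interior
  time points; with 1000 surrogates of a 900-day series that is ~2x10^7
  draws per scale, making threshold noise negligible relative to the
  classification noise.

## Problem sizes used in the shipped checks

The package's own test suite simulates at the design scale where the
question demands it (the simulation-refit calibration runs 9
individuals x 900 days x 10 seeds; spectral calibration uses a
21600-hour series with 1000 surrogates and 100 fresh noise replicates;
the full-pipeline direction check runs ten complete
simulate-measure-refit rounds) and at reduced scale for unit
properties (30-120 day series, 100-200 surrogates), keeping single
checks in seconds.

## Known limitations

* The wavelet support at the 24-h scale spans roughly ±1.5 days, so
  day-level on/off periodicity states blur into neighbouring days:
  isolated noise days between periodic days inherit significance.
  Measured MP is consequently a smoothed, slightly inflated version of
  the generating state sequence; effect *directions* survive, effect
  magnitudes on the measured scale are attenuated relative to the
  generating logit coefficients.
* With the reference DD coefficients the implied stationary DD level
  (~2.2 km) is small relative to a 3-km residual SD, so simulations at
  that residual scale censor heavily at the 0.1-km floor and
  slope-recovery is attenuated; at the package default (0.8 km)
  recovery is clean. See `coefficient_recovery()`.
* One ecosystem-wide NDVI value per day: no spatial forage
  heterogeneity, by design.
* The white-noise null is the classical one for this statistic; a
  red-noise (AR(1)) null would be stricter for slowly varying series
  and is out of scope.
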