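---
title: "Grey GM(1,1) modelling of short anthropometric series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey GM(1,1) modelling of short anthropometric series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greygrowth)
```

## The problem

National physical-fitness surveillance of Chinese preschool children (ages
3–6) produced five summary waves — 2000, 2005, 2010, 2014 and 2020 — of mean
height, weight, chest circumference and BMI by sex and age, plus
overweight/obesity detection rates for the first four waves.  Five points per
series is far too short for ARIMA-style modelling, but exactly the regime the
grey GM(1,1) model was designed for: a positive, near-exponential trend
observed at a handful of equidistant times.  This package implements that
model, its accuracy battery, and the full trend analysis and 2025/2030
forecasts built on it.

## The model

Write the prepared series as $x^{(0)}(m)$, $m = 1,\dots,n$.  GM(1,1) works on
the accumulated sequence (1-AGO) $x^{(1)}(m) = \sum_{k \le m} x^{(0)}(k)$ and
its adjacent means $z(k) = \tfrac12\{x^{(1)}(k) + x^{(1)}(k-1)\}$,
$k = 2,\dots,n$.  The whitened grey equation

$$x^{(0)}(k) + a\, z(k) = b$$

is solved for the development coefficient $a$ and grey constant $b$ by least
squares on the rows $(-z(k), 1)$.  `gm11()` solves the $2 \times 2$ normal
equations in closed centred form (slope $= \mathrm{cov}(z, y)/\mathrm{var}(z)$)
for numerical transparency; agreement with a generic `lm()` solve to
$10^{-9}$ relative is a test, not a dependency.  Negative $a$ means growth;
grey-theory guidance restricts short/medium-term prediction to
$a \ge -0.3$ (inclusive), exposed as `applicability()`.

Forecasts come from the restored response function

$$\hat x^{(0)}(m) = (1 - e^{a})\left(x^{(0)}(1) - \tfrac{b}{a}\right)
  e^{-a(m-1)}, \qquad m \ge 2,$$

whose leading coefficient is stored on the fitted object.  Slot 1 is never
restored.  The flat case $a = 0$ is handled as the analytic limit (constant
forecast $b$) because $x^{(0)}(1) - b/a$ is singular there.  Time slots are
unit steps whatever the calendar step, so $a$ is per survey cycle (five
years), matching the published $10^{-3}a$ magnitudes.

## Series preparation

Two preprocessing conventions precede every anthropometry fit:

* **Grid adjustment.**  The 2014 wave sits a year short of the five-year
  grid.  `to_equidistant()` moves the single off-grid point forward to the
  next grid year along the slope of the preceding gap:
  $x(2015) = x(2014) + \{x(2014) - x(2010)\}/4$.  The published adjustment
  (102.1 cm → 102.3 cm for boys' age-3 height) is only reproduced by this
  *extrapolation*; interpolating toward the 2020 value would give 102.07.
  No other missing-data handling is supported — the single off-grid
  penultimate wave is the only case that occurs.
* **Prefix augmentation.**  `add_prefix()` prepends an arbitrary positive
  value (default 10) so that all five real observations enter the
  regression.  The forecasts are provably invariant to the prefix value: a
  prefix shift $\delta$ shifts the whole accumulated sequence, hence every
  $z(k)$, by the constant $\delta$, leaving the regression slope — and so
  $\hat a$ — unchanged, moving $\hat b$ by exactly $\hat a\,\delta$, and
  leaving the restored coefficient
  $(1 - e^{\hat a})(x^{(0)}(1) - \hat b/\hat a)$ invariant.  The invariance is asserted to ten significant digits in the
  tests, which is why the default is a convention rather than a parameter
  worth revisiting.

Prevalence (rate) series have only four waves and are fitted **without** a
prefix: that convention reproduces the published boys' obesity projections
(11.0, 12.5, 14.1 % for 2020/2025/2030) exactly, while a prefixed fit
contradicts them.  The first observed wave (2000) then never receives a
fitted value; growth deltas fall back to the observed rate for that year,
which matches the published 2020−2000 difference (11.0 − 5.4 = 5.6).

## Accuracy battery

`gm11_diagnostics()` reports, over the regression rows $m = 2..n$: residuals
(actual − fitted), per-point precision $100(1 - |r|/x)$ %, mean relative
error and its complement (average relative precision), the posterior-variance
ratio $C = S_2/S_1$ ($S_1$, $S_2$ population standard deviations of the
originals and residuals), and the small-error probability $P$, the fraction
of centred residuals below $0.6745\,S_1$.  Conventions fixed here: population
(divide-by-$n$) standard deviations — $C$ is unaffected by the choice, $P$ is
not, and the population convention is validated by the worked example's
$C = 0.37$; residuals are centred before the $P$ comparison, the standard
convention, though the worked example cannot discriminate (it gives $P = 1$
either way).

Grades apply strict inequalities to each criterion — $C < 0.35/0.50/0.65$,
$P > 0.95/0.80/0.70$, precision $> 99/95/90$ % for levels 1–3, else level 4 —
and the overall grade is the *worst* criterion: the worked example is
Good (level 2) on $C$ alone despite level-1 $P$ and precision.

One caveat surfaced by the full fixture sweep: three near-flat series
(age-3 chest circumference for both sexes, boys' age-3 BMI) grade level 4
because their data standard deviation is so small that $C$ blows up even at
99.4 %+ precision.  $C$ measures residual variance *relative to signal
variance*, so it is intrinsically harsh on flat series; the published quality
claims for those tables rest on precision alone.  Relatedly, boys' age-3 BMI
fits with $\hat a > 0$ (a slight decline) — consistent with its published
negative 2020−2000 delta, though the source text asserts all development
coefficients are negative.

## Display conventions

Published values are rounded half-away-from-zero to one decimal
(`round_half_up()`); all internal computation is unrounded.  Growth rows are
computed **rounded-first**: the period delta is the difference of the rounded
endpoint values and the percent change divides by the rounded start value.
This is deliberate — the boys' age-6 height delta prints 4.1 where the
unrounded difference is 4.19 — and `cohort_summary()` averages the four
per-age rounded deltas (then rounds once more) to reproduce the headline
age-averaged increases (+3.6 cm height, +1.8 kg weight for boys over
2000–2020).  The annualized rate is the mean percent change divided by the
span in years (20), which reproduces the published height rate (0.16 %/yr);
no simple convention reproduces the published weight rate (0.46 %/yr), so
that figure is reported by the pipeline as computed (0.48) and not asserted.

Known irreproducible cells, all flagged (never silently corrected) by
`reproduce_tables()`:

* published 2030 anthropometry values sit 0.3–0.5 below the pure exponential
  extrapolation that reproduces every other column; no damping or re-fitting
  step is documented, so the model value is returned;
* girls' and boys' overweight and girls' obesity prevalence rows differ from
  every preprocessing variant tried; only the boys' obesity row reproduces;
* typographic errors in the source tables (a grey constant of 14.8 where the
  fitted column implies ~18.1; a non-monotone 22.5; a garbled percent cell)
  are carried verbatim with an errata sidecar, `printed_errata()`.

## Synthetic data and parameter recovery

`generate_series()` draws series from the model's own generative law: slot 1
is $x_1$, slots $m \ge 2$ follow the restored mean function with i.i.d.
Gaussian noise on the restored (observation) scale — the error structure the
residual analysis of the fitted survey models implies.  Positivity is
enforced by rejection with an explicit error, not truncation, so the
generative law stays honest.  Defaults mirror the survey regime: $n = 6$
slots, five-year steps from 2000, $|a| \le 0.3$.  Replicate $k$ of
`recovery_experiment()` is seeded `seed + k`, so any replicate is
reproducible in isolation.

What the generator does *not* emulate: sampling error correlated across ages
(each real series shares survey waves), measurement-protocol drift between
waves, and rounding of the published means.  Passing recovery tests
demonstrate estimator correctness under the model's assumptions, not that
real anthropometric change is exponential.

A subtlety worth stating precisely: even noise-free recovery is not exact.
On data generated from the restored exponential with ratio
$\rho = e^{-a}$, the adjacent-mean regression is *exactly affine* (zero
regression residuals) but recovers the (2,2)-Padé approximant
$\hat a = -2(\rho - 1)/(\rho + 1)$ of $a = -\ln\rho$, so
$|\hat a - a| \le |a|^3$, and $\hat b = b\,(\hat a/a)$ carries a relative
discretization bias $\approx a^2/12$.  At the anthropometric magnitude
($|a| \sim 10^{-2}$) both are negligible — the noise-free identifiability
test runs at $a = -0.002$, where the $b$ bias ($\sim 3\times10^{-7}$
relative) sits safely inside its $10^{-6}$ tolerance — but at the edge of the
applicability range ($|a| = 0.3$) the bias reaches 0.75 % and is a genuine
model property, not an implementation error.

## Problem sizes and determinism

Everything downstream of the generator is deterministic: the fitting
pipeline consumes no randomness, and `reproduce_tables()` is byte-stable
across reruns.  The recovery experiments use 500 replicates at the survey
noise scale and 300 per series length for the precision-versus-length sweep
— enough for the Monte-Carlo standard error on $\bar{\hat a}$ to be an order
of magnitude below the effects being checked, while the whole validation
runs in seconds.

## Limitations

Single-variable GM(1,1) only: no GM(1,N), Verhulst, rolling/metabolic or
fractional-order variants, and no background-value optimization.  Rates are
consumed as printed detection percentages, never derived from raw
anthropometry; no uncertainty intervals are produced (the source analysis
provides none).  The model's exponential form means long-horizon forecasts
should be read qualitatively; the applicability class exists precisely to
mark when even medium-term use is doubtful.
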