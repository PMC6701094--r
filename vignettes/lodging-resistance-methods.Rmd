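---
title: "Methods: quantifying stalk lodging resistance from wind-machine trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying stalk lodging resistance from wind-machine trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windlodge)
```

## The measurement model

A wind-machine trial subjects two 7-m rows of a maize cultivar to a stepped
sequence of generated wind speeds. The standard protocol rises in 5 m/s
steps to 10 m/s and in 2 m/s steps thereafter, up to the 30 m/s machine
safety cap, holding each level 30 s below 10 m/s and 19 s at and above
(`build_wind_schedule()` encodes this as its defaults — 12 levels in
total). The observable is discrete and censored: for each level, the
number of plants whose stalks failed while that level was held, plus the
number still standing when the maximum level ended.

`build_distribution()` normalizes these counts into a discrete lodging
distribution: point masses $p(v)$ at the generated levels $v$ plus a
censored mass at "$> S_m$". Two modelling commitments are made here and
used consistently everywhere downstream:

* **Masses are fractions in $[0,1]$, not percentages.** The
  lodging-resistance function $LR(s) = 1/(1 + \int_0^s p(v)\,dv)$ only
  stays in $[0.5, 1]$ — and the cumulative lodging index only attains its
  observed range (roughly 0.7–1.0 across real cultivars) — under the
  fraction reading.
* **Integrals over the distribution are sums of point masses.** Lodging is
  only observed at the generated levels, so
  $\int_0^s p(v)\,dv = \sum_{v \le s} p(v)$, and $LR$ is a right-continuous
  step function: a plant lodging at exactly $s$ counts against resistance
  at $s$, because failure is recorded the moment the level is reached.

## The four statistics

**Reduction index.** $RI_s = 1 - \bar u_{1,s}/\bar u_{0,s}$, where
$\bar u_{0,s}$ is the time-mean outlet speed over level $s$'s hold window
and $\bar u_{1,s}$ the time-and-station mean behind the canopy at one
measurement layer (bottom 0.2 m, middle 1.2 m, top 2.2 m).
`aggregate_reduction_index()` computes this per level from raw anemometer
logs. Negative values — a downstream gust exceeding the outlet mean — are
returned unclamped but flagged, so aggregation choices stay visible to the
caller.

**Failure wind speed.** The weighted L1 median of the lodging
distribution:
$FWS = \arg\min_{0 < s \le S_m} \sum_v p(v)\,|v - s|$.
The objective is piecewise linear with breakpoints at the atoms, so the
minimizer need not be an observed level (a bimodal cultivar's FWS can fall
between its two peaks). `failure_wind_speed()` therefore minimizes over a
regular candidate grid (default resolution 1 m/s) unioned with the
observed levels. Numerical choices:

* **Ties** (zero-slope stretches of the objective, e.g. two equal atoms)
  are broken toward the smallest minimizer, making the estimate the most
  conservative — lowest — failure speed consistent with the data.
  Minimizers are collected within a relative tolerance of $10^{-9}$ of the
  minimum.
* **Censored mass** enters the objective at the pseudo-speed
  $S_m + 2$ m/s — one default schedule step beyond the maximum. Survivors
  must pull the median upward somehow; placing them just beyond the tested
  range adds the least unobserved information. When the minimum is
  attained at the boundary $s = S_m$ *and* the censored mass outweighs the
  lodged mass, the FWS is not identified within the tested range and the
  result is reported as censored ("$> S_m$") rather than as an invented
  speed.
* The summation bound and the argmin bound are treated as the same
  quantity, the schedule maximum $S_m$: with data only at generated
  levels, no atom can exceed it.

**Lodging resistance and CLI.** $LR(s) = 1/(1+F(s))$ with
$F(s)=\sum_{v\le s}p(v)$, and
$CLI = \frac{1}{S_m}\int_0^{S_m} LR(s)\,ds$, computed as the exact sum of
segment widths times segment values of the step function — no quadrature
error, no grid parameter. The censored mass never enters $F$: it
represents survival beyond the tested range, and its effect on CLI is
exactly that it withholds mass from the lodged bins (an almost-unlodged
cultivar gets a CLI just below 1, not 1). The test suite cross-checks the
closed form against midpoint quadrature on a 0.01 m/s grid refined with
the breakpoints.

**Reliability.** For cultivars measured in both years,
$RMSE=\sqrt{\tfrac1n\sum_i (X_{2,i}-X_{1,i})^2}$ and
$nRMSE = RMSE / \bar X_1$ in percent, graded excellent/good/acceptable/poor
at 10/20/30%. A right-censored FWS enters as the value $S_m$; a cultivar
censored in both years thus contributes a zero difference. This is the
only convention under which the published FWS pairs (26→24, >30→>30,
16→20) give the published 10.76%, and it is stated prominently because it
biases the RMSE of heavily censored indices downward. Cultivars missing a
year are excluded pairwise. Trait association uses plain Pearson
correlations over cultivar means with no multiple-testing correction —
descriptive, not inferential.

## What the simulator emulates

`simulate_trial()` reproduces the data-generating shape of a trial:

* **Schedule**: the stepped protocol above, with 1 Hz anemometer sampling
  during each hold.
* **Attenuation**: per-layer reduction indices anchored at 2 m and 7 m
  from the outlet, linearly interpolated in distance
  (`attenuation_profile()`). The defaults are the open-field measurements:
  bottom 0.22→0.59, middle 0.02→0.65, top 0.02→0.66. Distances beyond 7 m
  are outside the validated range and error; below 2 m the near-anchor
  value applies.
* **Lodging**: each plant draws a breaking threshold from a normal mixture
  (component then threshold, in plant-index order — the reproducibility
  contract); at each level a standing plant fails when the attenuated
  **middle-layer** speed at its position reaches its threshold, the middle
  layer being ear height where the aerodynamic moment acts. Failures are
  recorded against the **generated** level speed, matching the machine's
  bookkeeping. An optional neighbour-knockdown probability models the
  domino effect observed qualitatively in the field; it defaults to 0
  because no rate has been measured.
* **Anemometer noise** is Gaussian, truncated at zero.

Defaults the experiments do not pin down are fixed once here: 84 plants
per trial (six plants per square meter in two 7-m rows 0.6 m apart),
plants evenly spaced along the row, and anemometer noise of 0.5 m/s.
The six presets in `preset_cultivars()` mimic the observed distribution
shapes: unimodal peaks near 20 and 26 m/s, bimodal mixtures at 12/24 and
20/30 m/s, and two nearly-all-censored cultivars (threshold means of 36
and 38 m/s, well above the schedule maximum).

What the simulator does **not** model: gust spectra and turbulence,
leaf-drag aerodynamics, between-plant mechanical variation beyond the
threshold mixture, and measured knockdown contagion. Passing tests
therefore demonstrate that the statistics recover the parameters of this
threshold model, not that the model captures every mechanism of field
lodging.

## Verification strategy and problem sizes

The suite checks each statistic against an independent oracle: brute-force
minimization of the L1 objective (outer-product evaluation at 0.01 m/s
resolution, 1000 random censored distributions), pointwise quadrature of
$LR$ against the closed-form CLI, loop-based RMSE/nRMSE, and hand-derived
values for every worked example. Property tests cover LR monotonicity and
bounds, stochastic-dominance monotonicity of CLI (mass moved to higher
speeds never lowers it), and conservation and bit-level determinism of the
simulator. Parameter recovery uses 1000-plant trials with unimodal
N($\mu$, 2) thresholds for $\mu \in \{16, 20, 24\}$ and 100 seeded
replicates each, asking the estimated FWS to fall within one 2 m/s
schedule step of $\mu$ in at least 95% of replicates; the smaller
in-suite simulations (30–50 replicates of 200-plant trials) keep the
default run in the tens of seconds.

## Known limitations

* FWS from machine trials tends to exceed estimates from natural-wind
  surveys: constant forced flow lacks gusts, and leaf drag is partly lost
  when leaves shred early in a test. The package computes the statistic;
  it cannot correct that physical bias.
* The censor conventions (pseudo-speed $S_m + 2$ in the L1 objective,
  censored-as-$S_m$ in reliability) are decisions validated only
  indirectly by reproducing the published censored entries; with heavily
  censored cultivars, FWS and its reliability should be read alongside
  CLI, which handles censoring without any convention.
* Published per-cultivar correlation coefficients based on replicate-level
  trait data cannot be reproduced from cultivar means alone; the package
  computes correlations from whatever resolution of data it is given.
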