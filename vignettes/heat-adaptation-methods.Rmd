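---
title: "Methods: urban heat adaptation scenarios and heat-attributable mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urban heat adaptation scenarios and heat-attributable mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`heatadapt` implements a city-scale health-impact analysis of urban heat
adaptation: how much do cool roofs, additional urban greenery, or their
combination lower daily temperatures across different urban morphologies,
who is exposed to those temperatures, and how many heat-attributable deaths
would the interventions avoid during a heatwave? The pipeline runs entirely
on synthetic data with known ground truth, so every stage is testable
end-to-end; this vignette records the models, the defaults and why they
were chosen, and what the synthetic design does and does not establish
about real data.

## The synthetic city

`gen_lcz_grid()` builds a concentric city on a 50 × 50 grid of 1 km pixels:
a compact mid-rise core (LCZ2) surrounded by compact low-rise (LCZ3), open
low-rise (LCZ6), sparsely built (LCZ9) rings, and rural land (codes ≥ 101)
outside. Ring radii default so that LCZ6 dominates the urban area — in
Belgium, and in many European countries, most of the urban population lives
in open low-rise neighbourhoods, and the default population densities
(`gen_population()`, lognormal noise around per-class means) reproduce that
dominance: compact pixels are denser, but open pixels are far more
numerous.

`gen_pixel_morphology()` expands a per-class morphology table (roof and
ground albedo, paved fraction ISA, urban fraction, building-surface-to-plan
ratio, plan area fraction, frontal area fraction, surface height, mean
building height) to per-pixel values with small multiplicative jitter.
The table values follow published Local Climate Zone parameter ranges;
they are configuration, not estimates, and the key structural constraints
are that compact classes are more paved, taller and denser than open
classes, and rural ISA is exactly 0 so the paved-fraction urban mask is
exact by construction.

`gen_baseline_temperature()` adds, on top of a regional background daily
series, a per-class urban heat island offset and Gaussian pixel-day noise.
The default offsets place the urban mean daily maximum about 2.9 °C above
rural during the five-day heatwave, and make the compact-vs-open gap larger
at night than by day — the two structural facts the downstream analysis
relies on. With offsets and noise set to zero the field is exactly the
background, which the tests exploit as a closed-form check.

## Scenario transforms and the cooling emulator

Scenarios are parameter transforms on pixel morphology:

* **Cool roofs** set the roof albedo of every built pixel to 0.85.
* **Greening** multiplies the unpaved fraction by 1.2 wherever the paved
  fraction strictly exceeds 0.20: `isa_new = 1 − 1.2 (1 − isa)`. The map is
  affine, so it commutes with averaging — a mean urban paved fraction of
  0.40 becomes exactly 0.28 — and a combination of threshold and increase
  that would drive ISA negative is an error, never a silent clip (with the
  defaults the smallest attainable value is 0.04).
* **Combined** applies both; the two commute because they touch disjoint
  fields.
* **Rural** replaces each urban pixel's class by the modal natural class
  among non-urban pixels within a radius (ties to the lowest code; global
  modal class when none is in range), with ISA set to 0.

"Exceeds 0.20" is read as a strict inequality for both greening
eligibility and the urban mask, one consistent rule; boundary pixels are
measure-zero under jitter. The mean urban albedo reported by
`summarize_scenario()` weights roofs by the plan area fraction
(`paf · roof + (1 − paf) · ground`); this is a documented convention — how
such city-mean albedos are aggregated is rarely stated in the literature —
not a reproduction target.

The atmospheric response is a transparent linear emulator
(`gen_scenario_temperature()`):

```
ΔT = −k_alb · Δroof_albedo · plan_area_fraction − k_green · Δ(1 − ISA) + ε
```

with separate coefficients for daily maxima and minima. Defaults are
`k_alb_max = 9.0`, `k_alb_min = 4.1` °C per unit plan-weighted albedo
change — equivalently 0.9 and 0.4 °C per 0.1 neighbourhood albedo
increase, the upper end of the range modelling reviews report — and
`k_green_max = 6.3`, `k_green_min = 9.6` °C per unit unpaved-fraction
increase, so greening cools nights more than days. Because the emulator is
linear, the combined scenario cools exactly as much as the sum of its
parts; a full atmospheric model shows sub-additive interactions (notably,
combined scenarios can cool daytime maxima *less* than cool roofs alone).
This non-additivity is deliberately out of scope: the package's claims
concern the downstream exposure and mortality analysis, not urban-canopy
physics, and tests assert only the orderings the linear emulator implies
(cool roofs beat greening by day, greening beats cool roofs by night,
compact zones gain more from cool roofs than open zones).

## Bias correction

Crowdsourced-style stations (`gen_stations()`) observe a synthetic truth
constructed as the model field minus a configured bias — by default a
constant +1.35 °C, the typical warm bias of crowdsourced urban networks,
optionally plus a linear function of the six morphological predictors
(urban fraction, building-surface-to-plan ratio, plan area fraction,
frontal area fraction, surface height, mean building height).

`fit_bias_model()` regresses the per-station-day bias (model − observed)
on those six predictors. Candidate regressors are a mean-only model,
ordinary least squares, ridge, lasso (both with a small fixed lambda grid)
and a random forest. Two design choices matter:

* **The target is the bias, not the temperature.** Predicting the bias
  makes the zero-bias case the exact identity and keeps the correction
  independent of the temperature scale.
* **The correction is one static spatial surface.** Predictors are
  per-pixel constants, so the learned map applies identically to every
  day; daily minima are never corrected (flagged as such in metadata) and
  rural pixels are untouched.

`select_model()` scores candidates by bootstrap: stations — not
station-days — are split 80/20 into training and held-out sets, so no
station contributes to both sides (days of one station share its pixel and
would leak). Ties go to the simpler model in a fixed order. The selected
kind is refitted on all stations.

`propagate_delta()` implements delta-change propagation: the corrected
scenario equals the corrected baseline plus the raw modelled
scenario-minus-baseline difference, element-wise. The identity
`corrected_scen − corrected_base = raw_scen − raw_base` holds to the last
bit and is tested as such.

## Population-weighted exposure

Exposure uses the heatwave-period mean of the daily statistic at each
pixel (`period_statistic()`), matching how scenario maps are usually
summarised, not day-resolved exposure. Populations are assigned whole to
their pixel's half-open 0.25 °C bin aligned to multiples of the bin width;
bin totals therefore sum to the masked population exactly, with no areal
interpolation (the synthetic population lives on the same grid).

`pop_weighted_threshold()` returns the highest temperature experienced by
at least a given fraction of the population: pixel values are sorted
descending and population accumulated, pixels sharing a value entering
together; no interpolation between pixel values is used. The median
cooling per LCZ (`lcz_cooling_curves()`) is the reduction experienced by
at least 50 % of that zone's population, population-weighted; the sign
convention is positive = cooling (baseline − scenario). The
baseline-scenario urban mask is reused for every scenario so the compared
population is fixed.

## The temperature–mortality model

Daily deaths are modelled as overdispersed counts whose log-mean is an
intercept, a natural cubic spline of same-day daily maximum temperature,
annual sine/cosine harmonics (two pairs) and a linear secular trend:

```
log E[deaths_t] = α + s(Tmax_t) + seasonality_t + trend_t,   Var = φ · mean
```

fitted by quasi-Poisson regression; the Pearson dispersion φ scales the
coefficient covariance. The spline is natural (linear beyond the boundary
knots, which sit at the observed range). The relative risk is recentred at
the minimum-mortality temperature (MMT), the 0.1 °C-grid argmin of the
fitted curve between the 1st and 99th percentile of the fitting
temperatures, ties to the lowest temperature; RR(MMT) = 1 exactly.

**Knot placement.** Internal knots default to the quartiles plus the 90th
percentile of the fitting temperatures. A sparser 50th/90th basis is
common but, in simulation against the generator truth, systematically
underfits the curvature around the risk minimum and displaces the fitted
MMT several degrees cold-ward; the quartile + 90th set recovers the
configured MMT of 24.0 °C within a few tenths of a degree on ten years of
daily data.

**Lag structure.** Only the overall (lag-cumulated) curve applied to
same-day maxima is implemented; the cross-basis lag dimension of
distributed-lag models is out of scope, a documented simplification — the
published city analyses this mirrors likewise apply the cumulative curve
to the daily maximum.

**The generator truth is itself a spline.** `true_erf()` builds, by
default, a natural-spline log-RR curve whose coefficients are solved from
three conditions: a stationary minimum at the MMT (24.0 °C), RR = 1.4 at
0 °C and RR = 1.7 at 35 °C — the heat anchor chosen so a five-day heatwave
in the mid-30s attributes roughly 40 % of deaths to heat, the magnitude
city-level heat-health assessments report. A U-shape is verified at
construction and non-U solutions are rejected. Two parametric alternatives
(`"cubic_heat"`, `"quadratic"`) are kept for oracle tests; being outside
the spline family, they carry an irreducible approximation bias of order
1 °C in the fitted minimum and are therefore not the default study
condition.

## Attribution and uncertainty

The attributable number over a window of observed deaths `D_t` and daily
maxima `T_t` is the standard forward attributable fraction:

```
AN = Σ_{T_t > MMT} D_t · (RR(T_t) − 1) / RR(T_t)
```

Days at or below the MMT contribute zero; the fraction lies in [0, 1)
whenever RR ≥ 1. The vectorised implementation accumulates with the same
floating-point semantics as a literal day-by-day loop (`rowSums`-based
basis products), so the oracle equality in the tests is exact, not
approximate.

`mc_ci()` draws coefficient vectors from a multivariate normal with the
dispersion-scaled covariance, recomputes AN per draw with the MMT held
fixed at its point estimate (reported intervals in this literature are on
AN, not on the MMT), and takes percentile bounds; zero covariance
collapses the interval onto the point estimate. Scenario comparisons
(`compare_scenarios()`) reuse the same coefficient draws for baseline and
scenario — pairing — so the avoided-deaths interval reflects the common
uncertainty and is never wider than the sum of the individual half-widths.
Percent reductions are avoided deaths over baseline attributable deaths,
rounded to one decimal in reports (deaths likewise).

**What the coverage check shows.** The test suite verifies that the 95 %
interval covers the analytic expected AN (Σ base_t (RR_t − 1) over hot
days) in 90–99 % of 200 generator replicates, each fitting two years of
daily data and evaluating a five-day warm spell (city maxima 32.5–35.6 °C)
with a metropolitan-scale death count (about 60/day). Two boundaries of
that regime are deliberate: the interval propagates coefficient
uncertainty only, with window deaths held fixed, so near-nominal coverage
can only be expected where coefficient uncertainty dominates the Poisson
noise of the window deaths; and the window lies inside the temperature
range the curve was fitted on. Outside that regime the interval is honest
but incomplete: beyond the hottest fitted day the natural spline
extrapolates linearly and can materially understate a steepening heat arm,
and for small windows the unpropagated death-count noise widens the true
error. Both are intrinsic to this class of health-impact assessment, not
artefacts of the implementation.

## Problem sizes and determinism

Simulation-backed tests use sizes chosen for statistical resolution: MMT
recovery uses ten years of daily data per seed over ten seeds (tolerance
±1.0 °C, at least 8 of 10); the flat-risk null uses ten-year fits over
twenty seeds; CI calibration uses 200 replicates of two-year fits with 500
Monte-Carlo draws; the attributable-number oracle runs 1 000 random
windows. The full pipeline on the default 50 × 50 city runs in a few
seconds. Every stochastic stage takes an explicit seed; the pipeline
derives per-stage seeds from one global seed (global × 1009 + a fixed
per-stage offset, kept below 2³¹), so stages can be rerun independently
and whole runs are bit-identical under a fixed configuration.

## Known limitations

* No atmospheric simulation: the linear emulator has no advection, cloud
  or wind feedbacks, and no sub-additivity between interventions; rural
  replacement simply removes the configured UHI offsets.
* The exposure-response has no distributed-lag dimension, no
  age/sex stratification, and no indoor-exposure or harvesting adjustment.
* Natural-spline extrapolation beyond the fitted temperature record
  understates an accelerating heat arm; attribution for record-breaking
  days hotter than anything in the fitting series should be treated as a
  lower bound.
* Stations are clean by construction; quality control of real
  crowdsourced networks is out of scope.
* Populations are whole-pixel; no dasymetric or areal interpolation.
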