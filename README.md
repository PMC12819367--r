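# heatadapt

Health-impact analysis of urban heat adaptation strategies, from city
morphology to avoided deaths. `heatadapt` asks: during a severe heatwave,
how much would cool roofs, a relative increase in urban greenery, or both
together lower daily maximum and minimum temperatures across different
urban morphologies (Local Climate Zones); who is exposed to those
temperatures; and how many heat-attributable deaths would the
interventions have avoided? It is written for urban-climate and
environmental-epidemiology researchers who want a fully testable,
self-contained version of this analysis chain: every input — LCZ map,
morphology, population, gridded temperatures, station observations, daily
mortality — is generated synthetically with known ground truth, so each
stage's statistical behaviour can be verified, not assumed.

## The models at the core

**Scenario transforms.** Cool roofs set every urban roof albedo to 0.85.
Greening applies a 20 % relative increase of the unpaved fraction wherever
the paved fraction ISA strictly exceeds 0.20:

    ISA_new = 1 − 1.2 · (1 − ISA)

so a mean urban paved fraction of 0.40 becomes exactly 0.28. A linear
emulator converts morphology deltas to cooling:
ΔT = −k_alb · Δroof_albedo · plan_area_fraction − k_green · Δ(1 − ISA),
with separate day/night coefficients (defaults equivalent to 0.9 °C of
daytime cooling per 0.1 neighbourhood albedo increase).

**Bias correction.** Daily-maximum model bias at urban stations is
regressed on six morphological predictors (candidates: mean-only, linear,
ridge, lasso, random forest; selected by station-level 80/20 bootstrap),
subtracted from the baseline as one static surface, and scenario deltas
are propagated unchanged (delta-change method):
corrected_scen = corrected_base + (raw_scen − raw_base), exactly.

**Exposure.** Population-weighted distributions of the period-mean daily
max/min in 0.25 °C bins, at-least-fraction exposure thresholds, and
per-LCZ population-weighted median cooling per scenario.

**Mortality.** Quasi-Poisson regression of daily deaths on a natural
cubic spline of daily maximum temperature plus seasonal harmonics and
trend; the relative risk RR(T) is recentred at the minimum-mortality
temperature (MMT, grid argmin of the fitted curve). Heat-attributable
deaths over a window are

    AN = Σ_{T_t > MMT} D_t · (RR(T_t) − 1) / RR(T_t)

with percentile confidence intervals from multivariate-normal coefficient
draws, paired across scenarios so avoided deaths
(AN_baseline − AN_scenario) carry a coherent interval.

## Worked example

The five numbered scripts under `analysis/` run the whole chain on the
default synthetic city (seed 1) and write their tables under `results/`.
The same computation is available programmatically:

```r
library(heatadapt)
art <- run_pipeline(default_run_config(seed = 1))
report_tables(art)$attribution_table
```

Stage 1 (`analysis/01_generate_city.R`) builds the city and prints its
baseline climate:

```
    stratum pixels population mean_tmax mean_tmin
1 all_urban   1020    2172777     36.14     21.80
2   compact    112     645889     36.48     22.92
3      open    908    1526888     36.10     21.66
4     rural   1480      88397     33.22     18.14

Urban-minus-rural mean tmax (the urban heat contribution): 2.9 degC
```

The urban mean daily maximum sits 2.9 °C above rural — the synthetic
city's urban heat contribution — and the compact-vs-open gap is larger at
night (1.26 °C) than by day (0.38 °C), the configured nocturnal
heat-storage signature.

Stage 2 applies the scenarios; the cool-roof run reports

```
Cool-roof cooling per 0.1 albedo increase: 0.9 degC (tmax), 0.4 degC (tmin)
```

Stage 5 (`analysis/05_mortality.R`) fits the exposure-response on a long
synthetic mortality record (true curve minimum at 24.0 °C), recovers the
MMT at 24.3 °C, and attributes deaths in the 5-day heatwave window (177
observed deaths):

```
           scenario   an ci_low ci_high avoided pct_reduction
           baseline 67.0   53.7    77.3     0.0           0.0
         cool_roofs 52.7   41.6    61.6    14.3          21.4
            green20 62.3   49.7    72.2     4.7           7.0
 green20_cool_roofs 47.7   37.4    56.1    19.3          28.8
              rural 41.1   31.9    48.6    26.0          38.7
```

Read: 67.0 of the 177 heatwave deaths (37.9 %) are attributable to heat
under the baseline; cool roofs would have avoided 14.3 of those deaths (a
21.4 % reduction of the attributable burden), greening alone far fewer
(7.0 %), and removing the city entirely — the rural counterfactual — 26.0
deaths (38.7 %).

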