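# stockhab

Length-based stock assessment and overwintering habitat suitability
modelling for data-limited, seasonally migrating fish stocks.

Many collapsed or data-poor fisheries have no age readings and no
absolute abundance index — only date-stamped length measurements and
coarse catch-by-location records. `stockhab` is aimed at assessment
scientists working with exactly that: it estimates growth, mortality,
exploitation and gear selectivity from length frequencies, and models
where a stock's overwintering habitat is (and how it has shifted under
a changing climate) from gridded environmental fields and winter
catches.

## What it implements

**Length-based engine.** Electronic length frequency analysis (ELEFAN)
fits the seasonalized von Bertalanffy growth function

L(t) = L∞ (1 − exp(−[K(t − t₀) + (CK/2π)(sin 2π(t − tₛ) − sin 2π(t₀ − tₛ))]))

by restructuring binned counts into signed peak scores and maximizing
the goodness score Rn = 10^(ESP/ASP)/10 along cohort growth
trajectories. Four search workflows are provided (K-scan, response
surface analysis, simulated annealing, genetic algorithm), plus the
full bin × MA × workflow scenario sweep. Downstream, a length-converted
catch curve gives total mortality Z; empirical estimators or a
literature value give natural mortality M; F = Z − M and E = F/Z follow
exactly; a logistic ogive fitted to back-extrapolated capture
probabilities gives t₅₀/t₉₅; and w = aL^b is fitted on logs.

**Habitat engine.** Per-variable suitability-index (SI) curves over
depth, winter sea surface temperature and salinity — an envelope
(Gaussian-with-baseline) form and a polynomial regression form — are
combined into habitat-suitability-index models by arithmetic or
geometric means. All 28 candidates (7 variable subsets × 2 forms × 2
combiners) are validated on held-out winters by R² and small-sample
AICc; habitat is classified at the 0.7/0.3 HSI thresholds into
optimal/average/poor with cos(latitude) area weighting; decadal area
changes are tested by one-way ANOVA with Scheffé contrasts; the winter
SST trend is an OLS slope.

**Synthetic data.** Seeded simulators generate (i) length samples from
a cohort population with known growth, mortality and selectivity and
(ii) environmental/catch grids whose expected catch is proportional to
a known true HSI — so every stage is testable by parameter recovery.

## Worked example

Simulate a two-year quarterly survey from a known population, fit
growth by simulated annealing, and derive mortality and exploitation:

```r
library(stockhab)

sc <- population_scenario(
  linf = 434, k = 0.43, z = 0.5, cv_length = 0.02, sel_l50 = 0,
  t_anchor = 0, n_per_sample = 500,
  sample_dates = c("2018-01-15", "2018-04-15", "2018-07-15", "2018-10-15",
                   "2019-01-15", "2019-04-15", "2019-07-15", "2019-10-15"),
  seed = 1)
lf <- bin_lengths(simulate_length_frequencies(sc), bin_mm = 10)

fit <- elefan(lf, method = "sa",
              bounds = list(linf = c(350, 520), k = c(0.25, 0.7)),
              seed = 2, control = list(n_temp = 120, n_prop = 40))
fit
#> ELEFAN SA fit (bin = 10 mm, MA = 5)
#>   Linf = 430.3 mm, K = 0.435 1/yr, t_anchor = 0.000, C = 0.00, ts = 0.00
#>   Rn = 0.488 (ESP = 53.67, ASP = 77.96)

cc <- catch_curve(lf, fit$params)
mort <- exploitation(cc, natural_mortality(fit$params, "user", m = 0.12))
mort
#> Mortality and exploitation estimates (1/yr)
#>   Z = 0.49 (SE 0.08)  M = 0.12 (user)  F = 0.37  E = 0.75
```

The fit recovers the generating curve (L∞ 430 vs 434 mm, K 0.435 vs
0.43) and the catch curve recovers Z = 0.49 against a true total
mortality of 0.5; E = F/Z = 0.75 would flag heavy exploitation.

The habitat side works the same way — simulate a grid whose catches
follow a known suitability structure, then let model selection find it:

```r
g <- simulate_environment_and_catch(habitat_scenario(seed = 1))
model <- hsi_select(g, train_years = 1971:1980, test_years = 1981:1982)
model
#> HSI model: regression-based arithmetic mean of {depth, sst}
#>   validation (train 1971-1980, test 1981-1982, n = 192): R2 = 0.4792, AICc = -781.95
#>   depth optimal range: 28.96-78.33
#>   sst optimal range: 17.61-21.13
```

Under the default 30% lognormal catch noise the selection recovers the
generating combiner (arithmetic mean) and variable set (depth + SST);
the optimal ranges bracket the true suitability modes (54 m,
19.35 °C). `habitat_timeseries()`, `decadal_anova()` and
`winter_sst_trend()` then quantify decadal habitat change, and
`run_pipeline()` ties both engines into one reproducible run.

## Package layout

- `R/vbgf.R`, `R/lfq.R`, `R/restructure.R`, `R/score.R`, `R/elefan.R` —
  growth model, length-frequency containers, ELEFAN scoring and search
- `R/mortality.R` — catch curve, M estimators, exploitation, ogive,
  length-weight
- `R/hsi.R` — SI curves, HSI combination, selection, areas, ANOVA, trend
- `R/simulate.R` — the two ground-truth simulators
- `R/io.R`, `R/pipeline.R` — CSV interchange and the end-to-end runner
- `vignettes/stockhab-methods.Rmd` — models, assumptions, design
  choices, limitations
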