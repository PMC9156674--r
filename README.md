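# firemosaic

Fire-regime reconstruction and *Callitris intratropica* demography for
savanna landscapes.

## What this package is for

In the frequently burnt savannas of the Australian monsoon tropics, the
fire-sensitive conifer *Callitris intratropica* persists in small
closed-canopy groves that suppress grass fuels and exclude fire. Because the
species is an obligate seeder with termite-resistant dead wood, its stand
structure records fire-regime history: where regimes shift toward frequent,
extensive fires, juveniles die, groves erode, and landscapes fill with
standing dead stems. `firemosaic` is aimed at fire ecologists and
conservation demographers quantifying such regime shifts and their
demographic consequences. It provides:

* **Burn mapping** from seasonal surface-reflectance composites: NBR =
  (NIR − SWIR)/(NIR + SWIR); seasonal dNBR (early: MAM→JJA, late: JJA→SON);
  subtraction of the all-year seasonal mean to remove static landscape
  features; burn masks at a strict dNBR > 0.75 cutoff.
* **Time-since-fire grids** (censored where no burn is on record) and
  **long-unburnt (> 5 yr) patch mosaics** via 4/8-connected components,
  summarized into annual regime tables.
* **Pre/post-intervention statistics**: two-period linear models with
  arcsine-square-root (proportions) and log (patch size) transforms, with a
  5-year-lagged threshold for the long-unburnt class.
* **Demography**: field size-class schemes, per-segment transect densities,
  an operational stand-status rule, and annualized survival
  (N₂/N₁)^(1/y) × 100.
* **Establishment dating**: the height–age curve
  age = −2.1 + 2.024·√height(cm), the five-ring pith estimator, Tucson .rwl
  I/O, and decadal establishment binning per transect segment.
* **Grass-fuel comparison**: dry-weight conversion, check-loss quantile
  regression (τ = 0.90 / 0.50) with bootstrap CIs and asymmetric-Laplace
  ΔAIC model comparison.
* **A Markov grove patch-dynamics simulator** over the states healthy /
  degraded / recovering / singleton / new / absent, forced by an annual burn
  probability *f*.
* **Seeded synthetic-data generators** for every input (composite stacks
  with known burn truth, clustered stem maps, survival histories, ring
  series, fuel tables), so the whole pipeline is testable with known ground
  truth.

## Worked example

Simulate a 25-year fire history whose dominant season flips from late to
early dry season in 2006, map it, and test for regime change:

```r
library(firemosaic)

set.seed(1)
mk_fires <- function(years, season, n_per_year = 2) {
  do.call(rbind, lapply(years, function(y) {
    f <- data.frame(year = y, season = season, amplitude = 1.0)
    f <- f[rep(1, n_per_year), ]
    f$footprint <- replicate(n_per_year,
      disc_footprint(runif(1, 200, 1300), runif(1, 200, 700), runif(1, 80, 160)),
      simplify = FALSE)
    f
  }))
}
fires <- rbind(mk_fires(seq(1996, 2005, by = 2), "late"),
               mk_fires(seq(2006, 2019, by = 2), "early"))
scn   <- fire_scenario(30, 50, cell_size = 30, years = 1995:2019,
                       fires = fires, noise_sd = 0.05, seed = 42)
land  <- gen_fire_landscape(scn)
stack <- map_fire_history(land$composites, cutoff = 0.75)
regime <- summarize_regime(stack)
compare_regimes(regime, intervention_scheme("dukaladjarranj"))
```

```
        variable    transform    slope     se      t        p n_pre n_post
1       mean_tsf     identity  7.05425 1.2391  5.693 2.13e-05     6     14
2  mean_patch_ha          log -0.07340 0.1136 -0.646 5.26e-01     6     14
3        p_total arcsine_sqrt  0.00817 0.0553  0.148 8.84e-01    11     14
4        p_early arcsine_sqrt  0.12852 0.0410  3.133 4.67e-03    11     14
5         p_late arcsine_sqrt -0.12035 0.0371 -3.247 3.55e-03    11     14
6 p_long_unburnt arcsine_sqrt  0.04392 0.0113  3.889 1.07e-03    11      9
```

The model recovers exactly what was simulated: a significant rise in early
burning and fall in late burning (on the arcsine-√ scale), no change in the
total proportion burnt, and a longer mean fire interval.

Longitudinal survival on a synthetic cohort tagged in 2006 and followed to
2019 (class-specific annual survival rates in the generator):

```r
census <- gen_survival_histories(survival_scenario(seed = 7))
survival_by_class(census, 2006, 2019)
```

```
  size_class n_start n_end raw_percent annualized_percent
1   juvenile     385     5         1.3               71.6
2 very_small      52    21        40.4               93.3
3      small      94    61        64.9               96.7
4     medium     166   124        74.7               97.8
5      large     175   147        84.0               98.7
6 very_large     220   123        55.9               95.6
```

`annualized_percent` is (N₂/N₁)^(1/13) × 100: juveniles collapse while large
trees survive at ≈ 99 %/yr. Regional fuel loads (medians 71 vs 112 g m⁻² in
the generator) compared by quantile regression:

```r
quads <- gen_fuel_samples(fuel_scenario(seed = 7))
compare_fuel_loads(quads, taus = c(0.9, 0.5), B = 2000, seed = 1)
```

```
  tau  coef ci_lower ci_upper delta_aic
1 0.9 153.0    101.7    233.3     114.1
2 0.5  31.9     15.4     44.9      17.7
```

The regional contrast is much larger at the 0.90 quantile than at the
median — the heteroscedastic signature quantile regression is used for —
and ΔAIC strongly favors the region model at both levels. Dating
primitives:

```r
round(age_at_height(100))          # 18 — years for a seedling to reach 1 m
establishment_year(1900, 100, 3)   # 1879 — innermost ring 1900, 3 missing rings, cored at 1 m
indicative_age(c(10, 30))$age_decade  # 60 140 — age-class boundaries at 10/30 cm D1.0
```

## Documentation

The methods vignette (`vignettes/firemosaic-methods.Rmd`) documents the
models and their assumptions, every tunable parameter with its default and
rationale, what the synthetic generators do and do not emulate, numerical
edge-case handling, and known limitations.
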