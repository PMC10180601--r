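# ringclim

Tree-ring chronologies, climate indices and drought resilience for
comparative dendroclimatology.

`ringclim` is aimed at forest ecologists who want to compare how co-located
tree species respond to climate — the kind of question asked when screening
drought-tolerant alternatives (e.g. *Cedrus libani*) against Central
European workhorse conifers (*Picea abies*, *Pinus sylvestris*). It covers
the full workflow from raw increment-core measurements to species-level
stress-response statistics, with a tidyverse-style interface: every stage
takes a data frame and returns a tibble.

## What it computes

* **Chronologies.** Cores → per-tree mean series (RGS) → raw species
  chronologies (RGC, sample depth ≥ 2, lag-1 autocorrelation Ar1) →
  detrended **growth index chronologies** (GIC). Detrending uses a
  penalised cubic smoothing spline whose stiffness is set in the frequency
  domain: amplitude response 0.5 at a wavelength of 67 % of the series
  length (Cook–Peters parameterisation),

  $$\lambda = \frac{1-a}{a}\,\frac{\cos 2\pi f + 2}{6(\cos 2\pi f - 1)^2},
    \qquad f = 1/(0.67\,n),$$

  indices are ratios $x_t/\hat g_t$, and the species chronology is Tukey's
  biweight robust mean with quality statistics Rbar and
  $EPS = n\bar r / (n\bar r + 1 - \bar r)$.
* **Climate indices.** From daily (optionally 10-min) meteorology: mean
  temperature, heat sum (> 20 °C), hot/frost/ice/rain day counts
  (Tmax ≥ 30, Tmin ≤ 0, Tmax ≤ 0 °C, PPT > 1 mm), mean daily-maximum
  vapour pressure deficit (Magnus $e_s$), Thornthwaite PET, and the
  3-month SPEI (log-logistic, probability-weighted moments) — per month,
  vegetation period (Apr–Sep) and previous winter (prev Oct–Mar).
* **Stress years.** Vegetation-period mean temperature ≥ 90th percentile
  and/or precipitation ≤ 10th percentile, with confirmation flags from hot
  days, heat sums, VPD, rain days and SPEI3 < −1.
* **Correlation functions.** Bootstrapped Pearson correlations (1000
  resamples, percentile 95 % CI) between a GIC and every climate cell from
  previous September to current September plus seasonal aggregates.
* **Resilience.** Per-tree Lloret indices around stress events
  ($Rs = RG_{SE}/\overline{RG}_{pre}$, $Rc = \overline{RG}_{post}/RG_{SE}$,
  $Rl = Rs\,Rc$; window widths 1 and 2), species medians, and group tests
  (Kruskal–Wallis + Dunn with Holm–Šidák adjustment; ANOVA + Tukey HSD for
  stand attributes).
* **Synthetic data.** A generator with known ground truth (seasonal AR(1)
  climate, engineered hot-dry years, negative-exponential age trend,
  species-specific monthly drivers) so that every stage has an end-to-end
  recovery test.

Formats: Tucson/RWL decadal files (`read_rwl()`/`write_rwl()`, 0.01 mm
units), long CSV, YAML run configs (`run_pipeline_config()`).

## Worked example

Simulate a study-shaped stand (three species, 27/17/13 trees, two cores
each, 1994–2019, drought years 2003/2012/2015/2018) and run the stages:

```r
library(ringclim)
library(dplyr)

climate <- simulate_climate(climate_gen_config(seed = 11))
cores   <- simulate_forest(forest_gen_config(seed = 12), climate)

trees <- average_cores(cores)
gic   <- build_gic(filter(trees, species == "C. libani"))
glance(gic)
#> # A tibble: 1 × 8
#>   species   n_trees first_year last_year mean_depth  rbar   eps     ar1
#>   <chr>       <int>      <int>     <int>      <dbl> <dbl> <dbl>   <dbl>
#> 1 C. libani      27       1994      2019         27 0.689 0.984 -0.0405
```

Rbar ≈ 0.69 and EPS ≈ 0.98 say the 27 trees share a strong common signal —
well above the conventional EPS > 0.85 acceptability threshold.

```r
idx    <- climate_indices(climate)
stress <- detect_stress_years(idx, study_years = 1994:2019)
filter(stress, stress) %>% select(year, tmean, ppt, hot_year, dry_year)
#> # A tibble: 4 × 5
#>    year tmean   ppt hot_year dry_year
#> 1  2003  16.2  182. TRUE     TRUE
#> 2  2015  14.9  202. FALSE    TRUE
#> 3  2018  17.7  201. TRUE     TRUE
#> 4  2019  15.0  473. TRUE     FALSE
```

The two engineered extreme years (2003, 2018) exceed both percentile
criteria; 2015 is dry-only and 2019 hot-only.

```r
cf <- correlation_function(gic, idx, seed = 13)
as_tibble(cf) %>% filter(significant) %>% arrange(desc(abs(r))) %>% head(5)
#> # A tibble: 5 × 7
#>   variable window      r  ci_low ci_high significant n_years
#> 1 ppt      FEB     0.694  0.466   0.851  TRUE             25
#> 2 spei3    APR     0.653  0.449   0.795  TRUE             25
#> 3 nrd      FEB     0.435  0.0629  0.732  TRUE             25
#> 4 nrd      AUG    -0.431 -0.711  -0.104  TRUE             25
#> 5 nrd      oct    -0.392 -0.668  -0.0572 TRUE             25
```

The strongest cell is February precipitation (r = 0.69) — exactly the
driver this synthetic species was programmed with (spei3 in April echoes it
because the 3-month window ending in April contains February).

```r
li <- lloret_indices(trees, events = c(2003, 2012, 2015, 2018), w = c(1, 2))
species_summary(li) %>% filter(index == "rs", w == 1, event %in% c("2003", "avg"))
#> # A tibble: 6 × 6
#>   species       index     w event value n_trees
#> 1 C. libani     rs        1 2003  0.831      27
#> 2 C. libani     rs        1 avg   0.883      27
#> 3 P. abies      rs        1 2003  0.535      17
#> 4 P. abies      rs        1 avg   0.495      17
#> 5 P. sylvestris rs        1 2003  0.313      13
#> 6 P. sylvestris rs        1 avg   0.539      13

glance(kruskal_dunn(filter(li, w == 1), "rs", "species"))
#> # A tibble: 1 × 5
#>       H    df  p_value n_reject alpha
#> 1  113.     2 3.45e-25        2  0.05
```

The cedar-like species resists the 2003-style drought best (median
Rs ≈ 0.83, i.e. a 17 % ring-width decline); the summer-precipitation-driven
species lose more because the drought year also starves their programmed
driver. The Kruskal–Wallis/Dunn test separates the species decisively.

`run_pipeline()` chains all stages and writes every table (chronologies,
index tables, correlation and resilience CSVs, stress-year and group-test
JSON, a parameter log) to an output directory; `autoplot()` methods and
`plot_response_indices()` give quick-look figures.

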