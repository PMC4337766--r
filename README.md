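# dielmove

Diel-scale movement behaviour of large herbivores from hourly GPS
telemetry.

Free-ranging savannah elephants adjust *how much* and *how regularly*
they move as forage conditions change, and their social rank shapes how
far they can adjust. `dielmove` quantifies both behaviours from hourly
GPS tracks and relates them to forage availability and rank:

* **Diel displacement (DD)** — the daily sum of hourly net
  displacements \(S^N\) (great-circle distances between successive
  hourly fixes on a 6371-km sphere), a proxy for daily energy
  expenditure. Failed fixes are linearly interpolated; days with fewer
  than 20 successful fixes are flagged invalid.
* **Movement predictability (MP)** — the proportion of a day's 24
  hours whose Morlet wavelet power at 1, 2 or 3 cycles/day
  significantly exceeds a white-noise bootstrap null (1000 surrogates,
  pointwise α = 0.05, variance matched to the individual's normalized
  displacement series). MP measures circadian regularity of movement.

Both metrics feed random-intercept GLMMs

```
g(E[n_ij]) = β0 + β1·NDVI_i + rank_j + NDVI_i:rank_j
             + φ1·n_{i-1,j} + φ2·n_{i-2,j} + b_j
```

with identity link for DD and logit link for MP (daily proportions
treated as binomial counts of 24 hours), fit by maximum likelihood with
`lme4`. Helpers provide likelihood-ratio tests, per-rank NDVI slopes,
high-vs-low slope contrasts and population-level prediction curves,
plus loess mean/CV trends and per-forage-category summaries. A
synthetic generator (tracks + NDVI + ranks with exported ground truth)
makes the whole pipeline testable without field data.

The package is aimed at movement ecologists working with regular
high-frequency telemetry of social species.

## Worked example

```r
library(dielmove)

# a synthetic study: 9 individuals, 400 days, known ground truth
ds  <- simulate_dataset(sim_config(seed = 42, n_days = 400))
res <- diel_pipeline(ds$tracks, ds$ndvi, ds$ranks,
                     seed = 7, n_surrogates = 500)

head(res$records, 3)
#> # A tibble: 3 × 9
#>   individual_id date       dd_km n_fixes valid     mp  ndvi forage_category rank
#>   <chr>         <date>     <dbl>   <int> <lgl>  <dbl> <dbl> <fct>           <fct>
#> 1 F01           2001-01-01 NA         23 FALSE NA     0.227 LFA             low
#> 2 F01           2001-01-02  1.65      21 TRUE   0     0.226 LFA             low
#> 3 F01           2001-01-03  1.70      21 TRUE   0.333 0.238 LFA             low

rank_slopes(res$dd_fit)
#>        low     medium   variable       high
#> 0.49635686 0.53600977 0.02321423 0.64512831

rank_slopes(res$mp_fit)
#>       low    medium  variable      high
#> 2.7082931 2.2022699 1.4754922 0.8329233

slope_percent_change(rank_slopes(res$dd_fit))
#> high
#>   30

category_summaries(res$records)$pooled
#> # A tibble: 3 × 5
#>   forage_category median_dd mean_mp n_days n_individuals
#>   <fct>               <dbl>   <dbl>  <int>         <int>
#> 1 LFA                  1.99   0.428   1397             9
#> 2 MFA                  2.13   0.539    832             9
#> 3 HFA                  2.38   0.669   1351             9
```

Each row of `res$records` is one individual-day: its DD in km, fix
count and validity (the first day here lost its first hour to the day
boundary, so it is incomplete and flagged), measured MP, the day's
NDVI, its equal-width forage category (LFA/MFA/HFA) and the
individual's rank. The slope tables give the NDVI effect per rank
level (reference "low" plus interaction terms): DD responds to NDVI
more steeply for high-ranked individuals (+30% over low in this run;
individual slope estimates at 400 days are still noisy) while the MP
response is markedly flatter for them (-69%) — the generator's
ground-truth pattern (+61% / -52%), recovered through the full
measurement pipeline. Median DD and mean MP both rise monotonically
across the three forage categories. `cv_trend()` and `loess_trend()`
give the descriptive mean and coefficient-of-variation curves against
NDVI.

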