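# expozone

Regionalization of mortality risk from environmental pollution exposure.

`expozone` is an R package for epidemiologists and spatial analysts who need
to go from a locality-level death registry plus pollution-factor rasters to a
mapped answer to the question *"how much of this disease burden is
attributable to living in the high-exposure part of the region?"*. It
implements the full chain:

1. **Cause screening** — crude mortality rates (`rate` = 100,000 · cases /
   population) and the mortality-rate ratio MRR = rate_local / rate_reference;
   causes are selected by how often their MRR exceeds 1 across years, with an
   exclusion list for causes whose aetiology is not pollution-specific.
2. **Exposure suitability** — a presence-background maximum-entropy model:
   the Gibbs distribution q(x) ∝ exp(Σ λⱼ fⱼ(x)) over background cells that
   maximizes the L1-regularized presence likelihood, fitted by cyclic
   coordinate ascent over linear/quadratic/hinge features of the covariates
   (distance to rivers, distance to industries, PM2.5, elevation). Outputs:
   raw and entropy-calibrated logistic suitability rasters, percent
   contribution per covariate, rank-based AUC.
3. **Zonation** — exact Fisher–Jenks natural breaks (dynamic programming,
   C++) classify the suitability surface into low / medium / very-high
   exposure zones.
4. **Association** — per-zone 2×2 tables give the odds ratio OR = AD/BC with
   Woolf (log) or linear 95% intervals, the relative risk (zone rate ratio),
   and the attributable fraction in the exposed, AF = 100·(OR−1)/OR.

Because registry extracts and satellite PM2.5 products are generally not
redistributable, the package also ships a **synthetic-region simulator**
(`region_config()`, `simulate_region()`, `simulate_association_study()`)
that generates rasters, rivers, industries, localities and Poisson mortality
with *known planted effects*, so every stage is testable end to end.

## Worked example

```r
library(expozone)

res <- run_pipeline(pipeline_config(seed = 3))
pc  <- res$causes[[1]]

pc$contribution
#> # A tibble: 4 × 2
#>   covariate       contribution
#>   <chr>                  <dbl>
#> 1 dist_rivers            67.9
#> 2 dist_industries        26.9
#> 3 elevation               2.96
#> 4 pm25                    2.27

pc$auc
#> [1] 0.752

pc$breaks
#> <jenks_breaks> k = 3, SSD = 8.67517 (n = 4096)
#>   breaks: 0.1934 | 0.3832 | 0.5298 | 0.8882

pc$summary
#> # A tibble: 3 × 6
#>    zone cases population  rate area_km2 n_localities
#> 1     1     4      44184  9.05     80.5           20
#> 2     2    10      47322 21.1     127.            25
#> 3     3    19      31731 59.9      48.8           15

pc$associations[[1]]
#> <association_result> zone 3 vs zone 1+2
#>   OR 3.915 (95% CI 1.963-7.810, woolf)
#>   RR 3.914 | AF 74.5%
```

Reading the output: proximity to rivers dominates the fitted suitability
model (67.9% of training gain), the logistic surface splits into three
natural-break zones, and the per-zone rates rise monotonically from 9 to 60
per 100,000. Living in the very-high-exposure zone carries 3.9 times the
odds of death from the simulated cause, and 74.5% of the exposed cases are
attributable to the exposure — close to the planted truth (rate ratio 6
across the full exposure gradient).

Direct use of the building blocks:

```r
mortality_rate(c(201, 13, 5), 515726)   # crude rates per 100,000
#> [1] 38.97  2.52  0.97
attributable_fraction(c(3.37, 4.79))    # AF (%) from odds ratios
#> [1] 70.3 79.1
fisher_jenks(c(1, 2, 10, 11, 20, 21), k = 3)
#> <jenks_breaks> k = 3, SSD = 1.5 (n = 6)
#>   breaks: 1 | 10 | 20 | 21
```

Every result type has `tidy()`/`glance()` methods and `autoplot()`
(`autoplot(pc$zones)` draws the zone map, `plot_associations()` a forest
plot). `run_pipeline()` accepts a YAML config and an output directory, and
writes rasters as Arc/Info ASCII grids, vectors as GeoJSON, tables as CSV,
and a `manifest.yaml` with the config hash and seeds; a thin CLI wrapper
lives at `inst/scripts/pipeline.R`. See the methods vignette
(`vignettes/methods.Rmd`) for the models, assumptions, and design decisions.

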