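# adaudit

Street-level audits of outdoor advertising — bus shelters, billboards,
totems, phone boxes — are one of the few ways to measure how much
unhealthy food marketing a neighbourhood is actually exposed to, and
whether that exposure tracks area deprivation. `adaudit` turns such an
audit from a spreadsheet exercise into a tested, reproducible pipeline for
public-health researchers and local-authority analysts weighing a
Healthier Food Advertising Policy (HFAP).

The package covers the full analysis chain:

* **Audit data model** — a validated four-level hierarchy (images →
  assets → adverts → products) over deprivation-ranked neighbourhoods,
  serialised as CSV tables plus a GeoJSON boundary file
  (`load_audit()`, `write_audit()`).
* **Area sampling** — stratification of neighbourhoods into Index of
  Multiple Deprivation (IMD) quintiles, selection of six areas per
  quintile with at most one per ward (deterministic priority-ward picks in
  the most deprived quintile), block-randomised visit order and a
  validation sub-sample (`assign_quintiles()`, `select_sample()`,
  `block_randomise()`).
* **Nutrient profile scoring** — the UK Food Standards Agency 2004/05
  Nutrient Profile Model. Per 100 g, "A" points from energy, saturated
  fat, total sugars and sodium (each 0–10) minus "C" points from
  fruit/vegetable/nut content (0/1/2/5 at >40/>60/>80 %), fibre and
  protein (each 0–5), with the protein cap when A ≥ 11 and FVN points < 5:

  *score* = A − (C~FVN~ + C~fibre~ + [C~protein~ if not capped])

  A food scoring ≥ 4, or a drink scoring ≥ 1, fails the model and is HFSS
  (high in fat, salt and sugar) (`npm_score()`, `score_products()`).
* **HFAP compliance** — brand-only food/drink adverts and adverts showing
  any HFSS product "would be non-compliant"; adverts whose assessable
  products all pass are compliant; otherwise not assessable
  (`classify_adverts()`).
* **Geographic exclusions** — geodesic point-to-boundary distances,
  exclusion of assets outside their area, and 5/10/20 m buffer
  sensitivity analyses (`filter_within_boundary()`,
  `buffer_sensitivity()`).
* **Statistics** — Cohen's kappa for dual-coder reliability, Pearson
  chi-square tests with a Cochran validity flag, per-quintile exposure
  tables and an asset-type × product-type advert matrix
  (`cohens_kappa()`, `chisq_independence()`, `exposure_tables()`,
  `run_exposure_tests()`).
* **Synthetic audits** — a seeded generator reproducing the statistical
  structure of a desk-scale city audit (30 areas, ~295 assets, ~437
  adverts, ~684 products), so every stage is testable without fieldwork
  data (`generate_audit()`, `generator_config()`).

## Worked example

Generate a synthetic audit with food advertising enriched in the two most
deprived quintiles, run the full pipeline, and inspect the exposure
analysis:

```r
library(adaudit)

cfg <- generator_config(seed = 2024,
                        food_enrichment = c(2, 1.8, 1, 0.6, 0.5))
bundle <- run_pipeline(run_config(generator = cfg), quiet = TRUE)

bundle$dataset
#> <audit_dataset>
#>   30 neighbourhoods, 357 images
#>   273 assets, 378 adverts, 577 products

bundle$tables$food_drink_by_quintile
#>   imd_quintile n_food_drink n_other pct_food_drink
#> 1            1           44      72             38
#> 2            2           30      47             39
#> 3            3           16      41             28
#> 4            4            8      95              8
#> 5            5            5      20             20

bundle$tests$food_drink
#> Pearson chi-square (independence): X2 = 32.41, df = 4
#>   p = 1.579e-06 (valid under Cochran's rule)

table(bundle$verdicts$status)
#>              compliant         not_assessable would_be_non_compliant
#>                     25                      4                     74
```

The quintile table counts food/drink adverts (any advert showing at least
one food or non-alcoholic-beverage product, or a food/drink brand-only
advert) against all other adverts; with the configured enrichment the
chi-square test rejects independence decisively, and the standardised
residuals in `bundle$tests$food_drink$std_residuals` show which quintiles
are above expectation. The verdicts table is the HFAP view: most food/drink
adverts here show at least one HFSS product or are brand-only, so they
would be restricted under a TfL-style policy.

Reliability statistics work on plain confusion tables:

```r
cohens_kappa(matrix(c(20, 10, 5, 15), 2))
#> Cohen's kappa = 0.40 (observed agreement 0.70, chance agreement 0.50, n = 50)
```

## Layout

```
R/                 implementation (data model, generator, sampling, NPM,
                   compliance, geo filter, statistics, pipeline)
inst/extdata/      checksum-pinned NPM band threshold table
tests/testthat/    unit, property and acceptance suites
vignettes/         methods vignette: models, assumptions, design choices
scripts/           acceptance script
```
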