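---
title: "Auditing outdoor food advertising: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing outdoor food advertising: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`adaudit` implements the analysis pipeline of a street-level audit of
outdoor advertising: photographs of advertising assets are coded into a
four-level hierarchy (images, assets, adverts, products), advertised food
and drink products are scored under the UK Food Standards Agency 2004/05
Nutrient Profile Model (NPM), adverts are classified against a hypothetical
Healthier Food Advertising Policy (HFAP), and exposure is compared across
area deprivation quintiles. This vignette explains the models and the
choices made where the design was genuinely open.

```{r setup}
library(adaudit)
```

## The audit data model

The sampling unit is a small administrative neighbourhood (an LSOA-like
area) carrying an Index of Multiple Deprivation (IMD) rank and quintile
(quintile 1 = most deprived) and a WGS84 boundary polygon. Within each
area, an *asset* is a physical advertising structure — one of fourteen
eligible types (bus shelters, billboards, totems, digital and static
free-standing displays, litter bins, phone boxes, and so on) with a
small/medium/large size class. An asset hosts one or more *adverts*
(digital assets and totems cycle through several creatives), and an advert
shows zero or more *products*, each coded into one of five groups: food,
non-alcoholic beverage, alcoholic beverage, gambling, other.

Three of the fourteen asset-type labels are not fixed by the audit frame we
mirror; `asset_type_labels()` pre-seeds eleven standard labels plus three
synthetic placeholders (`banner` — vinyl banners are a category typically
added after piloting — `lamp_post_banner`, `poster_board`). Users can
replace the placeholders or declare extra labels; undeclared labels are
rejected at validation so typos cannot silently create categories.

Coordinates are WGS84 lon/lat (the smartphone EXIF convention). Assets are
deduplicated by identifier, never by coordinates, because several images
can depict the same asset — which is also how missing GPS is resolved:
`impute_coordinates()` prefers the image's own EXIF fix, then a sibling
image of the same asset, then a manual lookup table, and otherwise flags
the image unresolved rather than failing.

## Nutrient profile scoring

The 2004/05 NPM scores a product per 100 g (drinks per 100 ml are treated
numerically identically, since all inputs here are expressed per 100 of
product). "A" points accrue from energy (kJ), saturated fat (g), total
sugars (g) and sodium (mg), each banded 0–10; "C" points from
fruit/vegetable/nut content (FVN%, scoring 0/1/2/5 at >40/>60/>80 %),
fibre and protein (each 0–5). The total is A minus the counted C points,
with the protein cap: when A ≥ 11 and the FVN component is below 5,
protein points are not counted. Foods fail (HFSS) at a total of 4 or more,
drinks at 1 or more.

Numerical choices:

* **Band edges are strict.** A value exactly at a threshold scores in the
  lower band; the test suite asserts this at every threshold of every
  component. Nutrient inputs are banded unrounded — no pre-rounding is
  applied before threshold comparison, so `satfat = 1.0` scores 0 points
  and `1.001` scores 1.
* **Thresholds are data, not code.** The band table ships as
  `inst/extdata/npm_thresholds.csv` and is checksum-pinned at load, so any
  divergence from the published model tables is auditable.
* **Fibre basis is explicit.** Both NSP (Englyst) and AOAC band tables are
  supported; batch scoring defaults to AOAC, matching modern labels, and a
  per-product `fibre_basis` field overrides the default.
* **FVN% hierarchy.** `derive_fvn_percent()` sums declared ingredient
  percentages of fruit/vegetable/nut entries (clamped at 100, because
  percentages of composite ingredients can double-count), falls back to a
  reference lookup matched on name, and otherwise assumes zero FVN —
  recording the provenance of every value.
* **Per-portion labels.** Out-of-home products declaring nutrition per
  portion are converted with a sourced product weight (manually weighed
  items preferred over handbook portion sizes); with no defensible weight
  the product is *not assessable* rather than guessed.

Alcoholic beverages, gambling and "other" products are outside NPM scope.

## HFAP compliance classification

Classification runs over *food/drink adverts*: adverts showing at least
one food or non-alcoholic-beverage product, or brand-only adverts for a
food/drink brand (brand recognition is an input flag, never inferred from
the brand string). Alcohol and gambling adverts are outside HFAP scope.
The precedence rule is:

1. brand-only ⇒ *would be non-compliant*;
2. else any HFSS product ⇒ *would be non-compliant* — an assessed HFSS
   product deliberately overrides missing data on sibling products, since
   the any-HFSS rule is unconditional;
3. else any unassessable food/drink product ⇒ *not assessable*;
4. else *compliant*.

## Geographic exclusions

Audit boundaries often run down the middle of roads, so assets are
photographed on both sides and those falling outside the area boundary are
excluded before analysis, with sensitivity re-runs at 5, 10 and 20 metre
buffers (`buffer_policy()`). Two numerical choices matter:

* **Distances are geodesic.** Point-to-boundary distances are computed on
  the WGS84 ellipsoid (via `geosphere`), which is metre-true at the 5–20 m
  scale of interest; buffering a polygon by *b* metres and testing point
  membership is equivalent, for points, to testing signed boundary
  distance ≤ *b*. Retention is therefore monotone in the buffer by
  construction.
* **The boundary is closed.** A point exactly on the boundary counts as
  inside: the exclusion targets assets *outside* the area, and GPS noise
  should not evict an asset standing on the line. An asset straddling two
  areas is assigned to the area containing its point and never
  double-counted.

## Area sampling

`assign_quintiles()` splits areas into five rank-ordered strata; when the
frame size is not divisible by five, the larger strata sit at the
most-deprived end (ceiling-first — any fixed rule would do; this one is
documented and monotone). Six areas per quintile are selected with at most
one per ward: the most deprived quintile deterministically takes the
lowest-ranked area of each designated priority ward (priority-ward
membership is treated as descriptive input, not re-derived from national
rank filters), while the other quintiles draw uniformly at random, with
the ward constraint enforced by rejection sampling (10 000-attempt cap,
then a ward-first fallback draw). Visit order is block-randomised into
five weekly blocks of six with every quintile represented in every block
(one quintile appears twice per block); with blocks smaller than the
number of quintiles the coverage constraint is vacuous and a seeded
permutation is used. A 10 % validation sub-sample (ceiling of the
fraction) is drawn for dual-visit reliability checks.

## Reliability and exposure statistics

Inter-rater reliability uses unweighted Cohen's kappa (categories are
nominal): observed agreement is the diagonal mass of the confusion table,
chance agreement the sum of margin products, and κ = (p~o~ − p~e~)/(1 −
p~e~); perfect agreement reports κ = 1 directly.

Exposure tests are Pearson chi-squares without continuity correction,
carrying a validity flag under Cochran's rule (no expected cell below 1
and at least 80 % of expected cells at or above 5 — the boundary case of
exactly 80 % passes). When the flag is false the p-value is reported but
explicitly not interpretable, mirroring audits where sparse HFSS counts
make a valid test impossible. The three planned tests are: (1) total
advertising — advert counts across quintiles against a uniform
expectation (a one-way goodness-of-fit, df = 4, since total exposure has
no second classification axis); (2) food/drink versus other adverts by
quintile (2×5 independence); (3) would-be non-compliant versus compliant
food/drink adverts by quintile (2×5 independence, not-assessable adverts
excluded). Standardised residuals (O − E)/√E identify which quintiles sit
above or below expectation. No multiple-testing correction is applied:
the three tests are planned and reported individually.

Reported percentages are uniformly rounded half-away-from-zero to
integers (`round_half_up()`). Product-type shares use the *advert*
denominator (the number of adverts showing at least one product of the
type, each type counted once per advert), which is the denominator under
which audit-style published shares are internally consistent; the
products-denominator alternative is deliberately not mixed in.

## The synthetic generator

`generator_config()` defaults encode the desk-scale study conditions: 30
areas in 5 quintiles; expected asset counts per quintile of
(74, 73, 50, 72, 26) — about 295 assets, heavy in the three
advertising-dense quintiles and light in the least deprived; multi-advert
totems and digital displays (1 + Poisson(3) adverts) giving roughly 437
adverts; 1 + Poisson(0.6) products per non-brand advert giving roughly 684
products; a product mix of ~15 % food, ~2 % soft drink, ~5 % alcohol, no
gambling; 17 % of food/drink adverts brand-only; 10 % of food/drink
products missing nutrition; and an HFSS fraction of 0.55 among assessable
food/drink products ("just over half"). Per-area asset counts are Poisson
— the audit frame reports no within-quintile dispersion, so equidispersion
is a modelling choice, not a reproduced fact.

Nutrient vectors are drawn from a two-component mixture — "treat-like"
(high energy/sugar/saturated-fat/sodium) and "staple-like" (moderate,
higher fibre/FVN) — and rejection-tuned until each product's realised NPM
verdict matches its Bernoulli(hfss_fraction) target, so both verdicts are
exercised and the realised HFSS share converges to the configured
fraction. Area polygons default to a rectangular grid (real boundary
GeoJSON may be substituted); `coordinate_jitter_m` adds metre-scale
Gaussian scatter that pushes edge assets across boundaries for the
geographic filter, and `generate_boundary_fixture()` constructs points at
exact geodesic offsets outside a polygon for buffer tests.

What the generator does **not** emulate: street-network placement (assets
are uniform within rectangles), advertising campaign cycles, correlated
content across an asset's adverts, demographic covariates beyond the IMD
quintile, and realistic brand/product names. Passing tests therefore
demonstrate that the *pipeline* behaves correctly under the assumed
statistical structure — not that real cities share that structure.

## Problem sizes and determinism

Every stochastic component is seeded and deterministic under its seed
(same seed ⇒ byte-identical output files). The test suite runs the NPM
scorer against an independent brute-force band oracle on 10 000 random
profiles; checks the food/drink exposure test's type-I rate (3–8 % at
α = 0.05) and power (≥ 80 % under strong Q1/Q2 enrichment) over 200 seeded
replicates each at the ~437-advert default scale; stresses the one-per-ward
sampling constraint over 1 000 seeds; and reproduces printed-share
arithmetic (e.g. 68/295 → 23 %) exactly on fixtures constructed to those
counts. These sizes were chosen so the full suite runs in about a minute
on a single core while leaving the binomial tolerance bands (3 standard
errors) tight enough to be informative.

## Known limitations

* GeoJSON support covers FeatureCollections of simple polygons (outer
  rings only); multipolygons and holes are not parsed.
* The NPM implementation targets the 2004/05 model only — not the 2018
  draft revision, front-of-pack schemes, or kcal-to-kJ inference.
* The reference FVN lookup matches on exact (case-insensitive) product
  name; fuzzy matching against a food-composition table is the caller's
  responsibility.
* Chi-square validity is a flag, not an automatic fallback: no exact or
  Fisher test is substituted when Cochran's rule fails, matching the
  reporting convention the pipeline mirrors.
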