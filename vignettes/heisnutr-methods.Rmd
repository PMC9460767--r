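---
title: "From household food purchases to nutrient availability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From household food purchases to nutrient availability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heisnutr)
```

## The problem

Household expenditure and income surveys (HEIS) record, for each sampled
household, the food and beverages bought over a short reference period —
typically seven days — with quantities and prices, classified into a few
hundred expenditure categories designed for price statistics rather than
nutrition. Mexico's ENIGH, the motivating case, uses 245 such categories, of
which 9 (tobacco, animal feed, food-preparation services, ...) carry no
nutritional value. Because these surveys are large, frequent, nationally
representative and rich in socioeconomic covariates, they are widely used to
approximate nutrient availability when dietary-recall data are unavailable —
but each study has tended to build its own ad hoc conversion from pesos and
kilograms to calories and micronutrients, making results hard to compare.

`heisnutr` implements one such conversion end to end, in a fixed, auditable
sequence, so that the same inputs always produce the same nutrient
estimates:

1. **Catalog accounting** — validate the category catalog, the
   food-composition records, and the food-to-category pairing; report
   coverage per composition source and enumerate nutritive categories still
   lacking any paired food (the trigger for another pairing round with
   additional sources).
2. **Conversion-table construction** — standardize every paired food to
   100 g of edible portion, collapse vitamin A into retinol activity
   equivalents, screen each category and nutrient for outliers with Tukey's
   fences, eliminate foods outlying in two or more nutrients, and aggregate
   the survivors by mean (or median).
3. **Purchase conversion** — for each household, quantity × edible fraction
   × density / 100, summed over purchases, divided by the reference days
   and by the household's equivalent adults.
4. **Survey estimation** — design-based means with 95% confidence
   intervals, overall, by year, and by income quintile, plus diagnostics of
   the food-away-from-home (FAFH) expenditure the conversion necessarily
   omits.

The human judgement embedded in pairing foods to categories is *not*
automated: the package validates and accounts for a pairing given to it; it
never invents one.

## The conversion table

**Standardization.** Composition sources report nutrients for arbitrary
portion masses. Every item is rescaled to a common basis of 100 g of
*edible* portion (`amount × 100 / portion_mass_g`), making items comparable
within a category regardless of how the source chose to tabulate them. The
six tracked nutrients and units are energy (kcal), protein (g), vitamin A
(µg RAE), vitamin C (mg), iron (mg) and zinc (mg) — the units in which
availability tables in this literature are printed.

**Vitamin A.** Retinol activity equivalents combine preformed retinol with
provitamin-A carotenoids at the standard IOM divisors: 1 µg RAE = 1 µg
retinol = 12 µg β-carotene = 24 µg other provitamin-A carotenoids. The
divisors are exposed as an argument for sensitivity analysis. A missing
component contributes nothing as long as at least one component was
measured; if all three are missing the vitamin A density is missing.
Missingness is always explicit: a blank cell is `NA`, never zero, because a
measured zero and an unmeasured nutrient mean different things downstream.

**Outlier screening.** Expenditure categories can pool quite dissimilar
foods, and composition sources occasionally contain entry errors, so the
category mean is protected with Tukey's fences: within each category and
nutrient, values outside
\[Q1 − 1.5·IQR, Q3 + 1.5·IQR\]
are flagged. Design choices a user should know:

- Quartiles use linear interpolation between order statistics at positions
  1 + (n−1)p (base R `quantile` type 7), the common default in scientific
  software. The estimator choice matters at the tiny group sizes typical
  here (2–8 foods per category).
- The fence interval is closed: a value exactly on a fence is not an
  outlier. Comparisons carry a relative numerical tolerance of 1e−10 so
  ties split only by floating-point rounding are never flagged.
- Flags are computed **once**, from all items; fences are not recomputed
  after exclusions. A single pass is deterministic and auditable; iterating
  fences on shrinking samples can cascade in small groups.
- An item flagged in **two or more** nutrients is eliminated entirely (its
  unflagged values leave with it); an item flagged in one nutrient stays,
  with only the flagged value excluded from that nutrient's aggregate. The
  threshold (default 2) is configurable.
- The edible fraction is aggregated with the same method (mean or median)
  as the nutrients; the sources are silent on this and symmetry is the
  least surprising choice.

Two caveats are inherent to quartile fences at these group sizes. First,
they are conservative: with continuous within-category variation they flag
legitimate tail foods at a non-trivial rate, so a drop log listing every
eliminated item accompanies every table — review it. Second, they can be
masked: two coincident gross contaminants in a four-item category can
inflate the IQR enough to hide each other; no quartile rule can unmask
that, which is why the synthetic generator injects at most one contaminant
per category (see below).

**Aggregation.** The category profile is the mean of the usable values
(median optionally, since vitamin A in particular is long-tailed and
mean-based tables can overstate it). A category whose every value for some
nutrient was missing or excluded is emitted with that density missing and a
warning — in production use it should be re-paired from additional sources.

## Purchase conversion

For a household *h* with purchases *q<sub>hc</sub>* (grams over the
reference period) of categories with edible fraction *e<sub>c</sub>* and
densities *d<sub>ck</sub>* (per 100 g edible), daily availability per
equivalent adult of nutrient *k* is

> A<sub>hk</sub> = Σ<sub>c</sub> q<sub>hc</sub> · e<sub>c</sub> ·
> d<sub>ck</sub> / 100 / days / AE<sub>h</sub>

with `days = 7` by default and AE<sub>h</sub> the sum of the household
members' equivalence-scale weights. Summation before division is fixed by
convention (the two orders are algebraically identical). Households with no
food-at-home purchases are *retained with zero availability* — the workflow
describes no exclusion, and dropping them would bias population means
upward; a caller can always filter beforehand.

The packaged default equivalence scale (0.70 under 4 y, 0.75 for 4–11 y,
0.80 for 12–17 y, 1.00 for adults) is explicitly illustrative: the official
scale for a given setting (e.g. CONEVAL's for Mexico) is licensed data the
package does not embed, and substantive analyses must supply it via
`equivalence_scale()`.

**FAFH.** Food away from home appears in these surveys as expenditure only
— no quantity, no composition — so no defensible conversion to nutrients
exists and the package refuses to attempt one: FAFH records are skipped
(with a count) during conversion, and a dedicated diagnostic
(`fafh_summary()`) quantifies the omitted budget share — participation,
constant-price daily expenditure at home and overall, and the mean
household-level FAFH share of food spending. Since FAFH routinely exceeds
20% of food budgets, availability series from this pipeline are lower
bounds, and year-to-year comparisons are only safe when the FAFH share is
stable — the diagnostic is there to check exactly that. Deflation is a
plain CPI ratio (`expenditure × base_index / year_index`).

## Survey estimation

HEIS samples are stratified two-stage designs with expansion factors, so
naive standard errors would be badly optimistic. The estimator is the
weighted ratio mean Σwy/Σw with Taylor-linearized variance treating PSUs as
drawn with replacement within strata — the standard convention for these
surveys. Confidence intervals use *t* critical values with
#PSUs − #strata degrees of freedom. Specifics:

- **Domains** (quintiles, subgroups) are estimated on the full design with
  out-of-domain households contributing zero residuals; their PSUs still
  count, so domain variances are not understated. The five quintile
  estimates, population-weighted, recombine exactly to the overall mean.
- **Lonely PSUs** (a stratum with a single PSU) contribute a squared
  deviation around the grand PSU mean, with a warning; with equal weights,
  one stratum and self-representing PSUs the estimator reduces exactly to
  the classical mean and t-interval, which the tests verify to 1e−12.
- **Income quintiles** are cut at weighted quantiles (p = 0.2, 0.4, 0.6,
  0.8) of income per equivalent adult, person-weighted (expansion factor ×
  household size), since the target tables are per-capita. The weighted
  quantile interpolates on cumulative weights at positions
  S<sub>k</sub>/(S<sub>n</sub> + w̄), reducing to the familiar (n+1)p rule
  under equal weights; ties on a cut point fall to the lower quintile.
- Whether published tables of this kind used *t* or normal critical values
  is typically unstated; *t* is the conservative choice and is what the
  coverage simulations certify.

## The synthetic generator

Nothing in the package requires microdata access: `sim_config()` +
`generate_catalog_and_foods()` + `generate_survey()` produce a full
ENIGH-like fixture set — catalog (245 categories, 9 non-nutritive),
multi-source composition items, stratified weighted households, purchases
with FAFH — together with a truth record (true category densities, true
population mean availability, true quintile ratios) that every estimate can
be checked against. Key generator choices:

- **Noise families are log-normal** (densities, quantities, incomes):
  positive support, right skew, mean-one parameterization
  (meanlog = −σ²/2) so expectations stay at the truth.
- **Density noise is small** (σ = 0.005 on the log scale). The recovery
  checks compare every recovered category×nutrient mean (~1,400 cells,
  sometimes only 3 retained items) against truth within 2%, which requires
  item noise of at most ~0.5%; synthetic items are therefore
  near-replicates of the category's typical food. Real composition tables
  have *much* larger cross-food spread — passing recovery tests certify the
  screening and aggregation machinery, not accuracy on heterogeneous real
  categories.
- **Contamination is isolated**: a category is hit with probability
  1 − (1 − rate)<sup>n</sup> (preserving the per-item marginal rate,
  default 5%) and exactly one of its items has 2–3 nutrients multiplied by
  10. This emulates sporadic entry errors and keeps "every contaminant must
  be caught" well-posed — coincident contaminants in tiny groups mask each
  other under any quartile rule.
- **The income gradient works through the category mix**, as it does in
  real data: each category is assigned the nutrient it is most dense in
  relative to the catalog average, and its purchased quantity scales
  linearly in the household's person-weighted income rank, with the slope
  set so the expected quintile-V/quintile-I availability ratio for that
  nutrient matches the configured target. Defaults mirror the published
  Mexico 2020 gradients (protein 1.24, vitamin A 1.46, vitamin C 1.83,
  energy and iron 1.07, zinc 1.10). True ratios are computed analytically
  and stored in the truth record.
- **Market vs. sample seeds**: the split of total purchases across
  categories and the price vector are drawn under `market_seed` (default:
  the main seed) so that repeated "survey years" can share one population
  truth while redrawing households.
- Every household buys every category (with noise); real purchase data are
  zero-inflated. This simplification keeps per-household truth exact and
  is irrelevant to the estimators, which are linear in purchases.

What the generator does **not** emulate: real category labels, ENIGH's raw
questionnaire units (quantities arrive already in grams), non-food
expenditure, intra-household allocation, and cooking losses (the tables are
for raw foods — vitamin C and zinc availability in particular will be
overstated relative to intake).

## Problem sizes and verification

The shipped tests and the acceptance script rerun the whole pipeline at
these sizes, chosen to exercise every code path at full catalog scale while
keeping a complete run in the minutes range: full 245-category catalogs
with 4–8 items per category for table construction; surveys of 8 strata ×
4 PSUs × 10 households (320 households, 30 categories) for estimator
checks; 500 replicate surveys for the 95% CI coverage simulation (observed
coverage ~95%, certified within 93–97%); 1,000 random small categories for
the brute-force Tukey oracle. Noise-free, gradient-free runs recover the
generator truth to ~1e−13, the floating-point floor of the summation.

## Known limitations

- FAFH nutrients are structurally missing; all availability levels are
  lower bounds on consumption.
- Purchases approximate consumption: stockpiling, waste, guests and
  intra-household distribution are invisible to a 7-day expenditure
  window.
- Tukey screening at 2–8 items per category is both conservative (drops
  real tail foods) and maskable (coincident outliers); the drop log exists
  so a human can audit every elimination.
- The conversion table is for raw edible portions; cooking and preparation
  losses are not modelled.
- Replicate-weight variance (BRR/jackknife), small-area estimation and
  formal trend tests are out of scope.
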