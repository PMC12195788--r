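---
title: "Methods: building and costing a healthy and sustainable food basket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and costing a healthy and sustainable food basket}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basketcost)
```

## The problem

Official basic food baskets (BFBs) anchor income poverty lines: a household is
poor when its income cannot buy an Orshansky multiple of a minimum,
calorie-sufficient food bundle. Such bundles prioritize caloric sufficiency
over nutritional quality and environmental sustainability. `basketcost`
implements the alternative: a *healthy and sustainable* basket that keeps the
EAT–Lancet food-group gram targets but distributes them across the foods a
low-income reference population actually buys, then prices that basket month
by month against the official BFB over a decade of consumer-price microdata.

The package covers five stages, each usable on its own:

1. **Basket construction** — consumption shares, target allocation, and
   edible-portion adjustment (`compute_group_shares()`,
   `allocate_group_target()`, `apply_fti()`, `build_basket()`).
2. **Nutrient profile** — per-item contributions and subgroup/grand totals
   with Atwater energy shares (`attach_profiles()`, `aggregate_totals()`,
   `macro_percentages()`).
3. **Price panel** — splicing CPI base-year segments, outlier screening,
   monthly min/mean extraction, nearest-neighbour imputation
   (`standardize_and_splice()`, `screen_outliers()`, `monthly_stats()`,
   `impute_missing()`).
4. **Costing and comparison** — monthly minimum-price costing, USD
   conversion, seasonal gap analysis, poverty thresholds
   (`basket_cost_monthly()`, `to_usd()`, `compare_costs()`,
   `poverty_thresholds()`, `summarize_period()`).
5. **Synthetic inputs** — seeded generators emulating the household survey,
   the CPI price observations, the exchange rate and the reference cost
   series, each returning its truth labels (`gen_*()`, `sim_config()`).

`run_pipeline()` chains all stages from a single config.

## Basket construction

For each food subgroup $s$ with daily gram target $T_s$, item $i$'s share is
its fraction of the reference stratum's purchased mass,
$w_{is} = q_{is} / \sum_j q_{js}$, and its consumed allocation is
$g_{is} = w_{is} T_s$. Shares are computed on purchased **mass**, not
expenditure, because the share's job is to preserve the physical consumption
pattern; an expenditure column can be substituted through the `weight`
argument when a survey reports spending only.

Purchased grams follow from the food transformation index (FTI), the ratio of
prepared/edible mass to purchased mass: $p_{is} = g_{is} / f_i$. A factor
below 1 (peeling losses) raises the purchase requirement; above 1 (water
uptake while cooking rice, pasta, pulses) lowers it.

Choices worth making explicit:

* **Item retention.** Every recorded item is kept by default
  (`min_share = 0`); a "most representative items" selection is available as
  a cumulative-coverage cutoff (`coverage`), since published baskets rarely
  state an explicit share floor.
* **Marginal subgroups.** A subgroup whose recorded mass is negligible is
  excluded outright (zero allocation), the treatment nuts and seeds receive
  in the packaged basket. The default trigger is *relative* — less than 0.1%
  of the stratum's total recorded mass — because a relative rule survives
  changes in survey size and units where an absolute gram threshold silently
  breaks; an absolute `min_subgroup_g` knob exists for users who have one.
* **Duplicate names.** An item can live in two subgroups (cucumber appears
  among both vegetables and fruits, with different transformation factors);
  all lookups are therefore scoped by `(subgroup, item)` with an item-level
  fallback.
* **Rounding.** All arithmetic is carried unrounded; 2-dp rounding happens
  only in print methods and serialized reports. The packaged composition
  fixture reproduces the published purchased-grams cells within 0.02 g —
  the residue of the source table's own printed rounding. Two quirks of that
  table are handled deliberately: the printed grams-to-consume columns of
  three subgroups miss their targets by 0.01 g (shares are renormalized, as
  the share contract requires), and the melons adjustment factor is stored
  as 0.52, the value its printed purchased grams and the fruit subgroup
  total are actually consistent with (the factor column prints 0.51).

## Nutrient profile

Per-item contributions are linear: grams/day ÷ 100 × value per 100 g. The
nutrient table declares whether its values refer to 100 g of prepared
(consumed) or as-purchased food; the default is consumed, applied to
`grams_consume`, since the FTI already owns the purchase-side correction.
Macronutrient energy shares use Atwater general factors 4/4/9 kcal/g
(configurable). The three percentages need not total 100: fibre, organic
acids and database rounding leave a remainder, and the packaged totals table
reproduces its printed percentage row within 0.02 percentage points (the
lipid share recomputes to 32.37 against a printed 32.36).

The packaged per-item nutrient table is **synthetic**: the source analysis
reports only subgroup totals, so per-100 g values are back-solved uniformly
within each subgroup such that aggregation over the packaged grams
reproduces every printed subgroup row exactly. It exists so the aggregation
machinery is testable end-to-end; real analyses should supply a food
composition table.

## Price panel

**Splicing.** CPI segments collected under different base years are linked
into one continuous series per item. Within each chronologically adjacent
pair the later segment is authoritative: the earlier segment's prices are
rescaled by the ratio of the two segments' monthly mean prices over their
overlap months, and the earlier segment's overlap observations are dropped.
Chaining runs backwards from the latest segment, so the whole series lands
on the current base-year level; an item absent from the overlap passes
through unscaled.

**Outlier screening.** The primary mechanism is an explicit admissible range
per item, the role national reference price guides play in practice;
observations outside `[low, high]` are flagged `corrected` and excluded from
monthly statistics (never deleted). Items without a range fall back to a
robust self-range — median ± `k`·MAD (default `k = 5`) over a rolling
12-month window. The fallback is honest but imperfect on strongly seasonal
series: the window mixes seasonal swing into the MAD, and over tens of
thousands of observations a handful of ~5-MAD noise draws will cross the
threshold (measured false-flag rate ≈ 3×10⁻⁴ per observation at the
generator's default noise). That is why the closed-loop zero-false-removal
check is run against reference ranges, which separate 10× outliers from
inliers with a structural margin, while the fallback carries a recall test
and a bounded false-flag rate.

**Monthly statistics and imputation.** Retained observations collapse to the
monthly mean and minimum per item (the minimum being the official costing
basis). Missing item-months inside the analysis window are filled with the
temporally nearest observed month of the same item, averaging the two
neighbours on an exact tie; observed cells are never altered, so imputation
is idempotent, and provenance (`observed`/`imputed`/`corrected`) is carried
per cell. The cited "nearest-neighbour" method is ambiguous between temporal
and cross-sectional neighbours; the temporal reading is the default, and a
donor-item variant (most-correlated item's profile, level-rescaled) is
available as `method = "donor"`.

**Windows.** Months are closed integer intervals; April 2014–December 2023
spans 117 calendar months. The source analysis counts "128 months" for the
same window; the arithmetic here is exposed as configuration and the
discrepancy left unresolved rather than papered over.

## Costing and comparison

Monthly basket cost is
$\sum_i \mathrm{grams}_i/1000 \times \mathrm{price}_{im} \times d_m$ with
$d_m$ the month's calendar days (a fixed-30-day convention is available; the
calendar convention is the one that reproduces the published April 2014
daily-USD figures of 2.10 and 2.36 from the published monthly figures). USD
conversion divides by the month's mean daily exchange rate. Gaps are
$100\,(c^A_m - c^B_m)/c^B_m$ with the window mean, the extreme months, and a
calendar-month seasonal profile reported together. Poverty thresholds scale
the basket cost by the Orshansky multiplier (default 2.68) with the extreme
line at two-thirds.

## What the synthetic generators emulate — and what they do not

The household survey, CPI microdata, official reference costs and central
bank exchange rates behind the original analysis are not publicly deposited,
so the package ships generators that reproduce their *statistical shape*:

* **Survey** — per-subgroup truth shares drawn from a Dirichlet concentrated
  on geometrically decaying weights (`share_decay = 0.8`,
  `share_concentration = 150`), giving one dominant item around 15–30% and a
  long tail, the documented shape of low-income purchase patterns; household
  purchases scatter around those shares (`household_concentration = 50`,
  lognormal mass, sdlog 0.3). Aggregated shares converge to truth
  (max error < 0.01 by n = 10,000 households).
* **Prices** — multiplicative level × trend (4%/yr) × item-phase sinusoidal
  seasonality (5% staples, 15% fresh produce, reflecting the stronger
  seasonality of fresh food) × lognormal monthly (3%) and per-outlet (5%)
  shocks, 4 observations per item-month; base-year breaks in January 2014
  and 2019 with lognormal level shifts (sd 0.1) and a 3-month reporting
  overlap; 5% missing item-months; 2% outliers at 10×. Every injection is
  labelled.
* **Exchange rate** — a daily geometric random walk (level 800, daily log-sd
  0.002).
* **Reference pair** — a reference cost series and a partner carrying a
  seasonal premium, by default mean 13.9% with amplitude 7.2 percentage
  points peaking in October (so the peak is ≈21.1% and the opposite month
  ≈6.7%). The default window covers whole calendar years so the configured
  mean premium *is* the window-mean truth the recovery test targets.

They deliberately do **not** reproduce Chilean price levels, inflation
history, CPI weighting, or the within-year premium asymmetry of the real
series (the published trough falls in December, not at the sinusoid's
antipode). Passing closed-loop tests therefore demonstrates that the
pipeline recovers known structure of the right shape — not that it
reproduces the historical cost series, which requires the restricted inputs.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the fixture reproductions on
the full 65-item basket, gap recovery on 120 synthetic months, imputation
oracle checks on panels up to 5 items × 12 months, screening recall on a
4-year single-segment panel (~11,600 observations; screening follows
splicing in the pipeline, so its input is free of base-year shifts), and
share recovery at 10,000 households. Shares must sum to 1 within 1e-9 after
renormalization; subgroup consumed totals conserve targets to 1e-9; grand
nutrient totals equal subgroup sums exactly; ties in imputation average the
two neighbours; all generators restore the caller's RNG state.

## Known limitations

* Each item has one national price series; regional price dispersion is out
  of scope.
* The official reference basket's own composition is never re-derived — its
  published monthly cost is an input.
* The donor-item imputation variant needs ≥ 3 common observed months and
  falls back to temporal imputation otherwise.
* Energy shares assume Atwater general factors; specific foods' metabolizable
  energy can deviate.

## A worked end-to-end run

```{r, eval = FALSE}
library(basketcost)
res <- run_pipeline(list(seed = 1, start = "2014-04", end = "2023-12"),
                    out_dir = "run1")
summary(res$basket)          # purchased grams per subgroup
res$nutrient_totals          # energy and macronutrients, with TOTAL row
res$gap                      # mean gap, widest and narrowest months
res$thresholds$poverty_line  # Orshansky-scaled poverty line
```
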