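# omega3intake

Database-driven assessment of dietary omega-3 fatty acid supply, for
nutrition researchers and food-safety risk assessors working with food
composition tables and stratified consumption surveys.

## What it computes

The package implements a screening-level
concentration-times-consumption exposure model for the three dietary
omega-3 fatty acids — α-linolenic acid (ALA, 18:3 n-3) from plant foods
and EPA/DHA (20:5 / 22:6 n-3) from aquatic foods:

- **Omega-3 content** of a food, in g per g food:

  `content = (ALA + EPA + DHA) / (SFA + MUFA + PUFA) × fat fraction`

  i.e. the omega-3 share of identified fatty acids times the total fat
  content. Contents are display-rounded half-up to 2 decimals and
  classified into bands: low (< 0.01), moderate (0.01–0.02), high
  (> 0.02 g/g).

- **Daily minimally required consumption (DMRC)**, the grams of a food
  needed per day to meet a recommendation:

  `DMRC = target / content`

  against the NIH adequate intakes for ALA (1.6 g/day adult men,
  1.1 g/day adult women, age-specific values for children) and the
  WHO/AHA/EFSA/DGA EPA+DHA tiers (250 / 500 / 1,000 mg/day), with an
  optional ~15% ALA→EPA+DHA metabolic conversion.

- **Stratified population intake**: for each sex × age stratum and food
  category, `intake statistic = consumption statistic (g/day) ×
  category-mean content (g/g)` at 100% assumed bioavailability, summed
  over categories (ALA ← oils, nuts/seeds; EPA+DHA ← fish, crustaceans,
  mollusks) and flagged adequate when the mean / P50 / P95 statistic
  reaches the applicable recommendation.

Reference composition tables for 126 Taiwanese foods (23 edible oils,
19 nuts/seeds, 48 fish, 21 crustaceans, 15 mollusks, compiled from the
Taiwan FDA Food Nutrient Database) ship with the package, together with
published stratified intake tables used as consistency fixtures and a
seeded log-normal generator of synthetic consumption surveys, so the
whole pipeline is testable without external data.

## Worked example

```r
library(omega3intake)

oils <- bundled_composition("edible_oil")
scored <- score_content(oils)
rank_by_content(scored, 3)
#>    rank food_id        name         category   content_exact content_display band
#> 1     1 edible_oil_001 Flaxseed oil edible_oil         0.535            0.54 high
#> 2     2 edible_oil_002 Walnut oil   edible_oil         0.136            0.14 high
#> 3     3 edible_oil_003 Rapeseed oil edible_oil         0.101            0.1  high

minimal_required_consumption(rank_by_content(scored, 1), target = 1.6)
#>   name         content_exact target grams_exact grams_rounded
#> 1 Flaxseed oil         0.535    1.6        2.99             3

band_distribution(score_content(bundled_composition("crustacean")))
#>   category band     count fraction
#> 1 all      low         17    0.810
#> 2 all      moderate     4    0.190
#> 3 all      high         0    0
```

Reading: flaxseed oil is 0.54 g omega-3 per g (57.7% of its fatty acids
are omega-3, at 92.8% fat), so about 3 g/day covers an adult man's
1.6 g/day ALA recommendation; 17 of 21 crustaceans (81%) sit below
0.01 g/g and are inefficient omega-3 sources.

The full pipeline — loading, QC against the listed contents, scoring,
ranking, bands, DMRC tables at every target, seafood-serving check, and
stratified intake with adequacy flags — runs as one call:

```r
report <- run_assessment(assessment_config(seed = 1), out_dir = "reports")
```

which writes machine-readable TSVs, a human-readable `summary.txt` and a
`run_log.txt` to `reports/`. A thin command-line wrapper lives at
`inst/scripts/omega3-report.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the complete assessment from scratch
against the installed package — bundled composition tables plus a
seeded synthetic consumption survey — and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/omega3-assessment.Rmd` documents the model and its
assumptions, the rounding and banding conventions, the recommendation
registry, what the synthetic generator does and does not emulate, and
known limitations.
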