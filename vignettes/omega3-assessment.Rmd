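---
title: "Assessing dietary omega-3 supply from composition and consumption databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing dietary omega-3 supply from composition and consumption databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omega3intake)
```

## The problem

Omega-3 fatty acids — α-linolenic acid (ALA) from plant foods and the
long-chain EPA and DHA from aquatic foods — are under-consumed in many
populations, but whether a *particular* population meets the
recommendations depends on two data sources that rarely live together:
a food composition database (how much omega-3 each food carries) and a
consumption survey (how much of each food people eat, by sex and age).
`omega3intake` joins the two in the standard screening-level exposure
model used in dietary risk assessment: a deterministic point estimate,
concentration × consumption, at assumed 100% bioavailability.

## The content model

For a food with fatty-acid masses per 100 g (saturated SFA,
monounsaturated MUFA, polyunsaturated PUFA, the omega-3 triad counted
inside PUFA) and fat fraction $f \in [0,1]$:

$$\mathrm{content} \;=\; \underbrace{\frac{\mathrm{ALA}+\mathrm{EPA}+\mathrm{DHA}}
{\mathrm{SFA}+\mathrm{MUFA}+\mathrm{PUFA}}}_{\text{share of fat}} \times f
\qquad [\text{g omega-3 / g food}]$$

Composition sources often print the share directly; both routes are
supported and are algebraically identical (`score_content()` accepts a
share column or derives it from a profile via `omega3_share()`, and a
property test asserts the two paths agree to machine precision). The
content is total omega-3 even when a food is evaluated against an
EPA+DHA recommendation, following common reporting practice for aquatic
foods, whose omega-3 is overwhelmingly long-chain; `epa_dha_only = TRUE`
switches to strict EPA+DHA scoring when profiles are available.

### Rounding and banding

Printed tables carry 2-decimal contents rounded **half-up**
(`round_half_up()`), not the round-half-even of `base::round()`. The
choice is observable: several bundled crustaceans and mollusks with
exact contents in 0.005–0.010 g/g are printed as 0.01, which only
half-up reproduces. Content bands are defined **on the display value**:
low < 0.01, moderate 0.01–0.02, high > 0.02 g/g. Banding on the exact
value would demote those same boundary species and contradict the
published band counts (17/21 low crustaceans, 11/15 low mollusks).
Ranking, by contrast, uses the exact content, with deterministic
name-ascending tie-breaks.

### Quality control

`validate_and_qc()` recomputes every listed content from its own share
and fat columns. On the bundled fish table three rows — Runner,
Silverfish, Yellow croaker — cannot be reproduced from their printed
inputs (e.g. 18.3% of 2.0% fat is 0.004 g/g, not the listed 0.02);
they are reported as `mismatch` findings and otherwise left as printed.
No override is invented. `info` findings flag contents within half a
display unit (0.0005 g/g) of a rounding cut, where a different rounding
dialect would change the display, and table-level notes (the oils table
lists 23 rows where its source narrative says 22).

## Recommendations and minimal required amounts

`reference_intakes()` seeds the registry: NIH adequate intakes for ALA
by life stage (0.32 g/day at 0–6 months rising to 1.6 / 1.1 g/day for
adult men / women; 1.4 and 1.3 g/day in pregnancy and lactation, which
override the sex-age lookup) and EPA+DHA recommendations (WHO and AHA
250–500 mg/day, EFSA 250 mg/day, DGA ≈250 mg/day via 8 oz seafood per
week). Age intervals are half-open and lower-inclusive on the published
labels, so exact boundary ages (13, 18) resolve to the younger group —
the sources leave the boundary unstated and a deterministic rule is
required; every age in 0–120 years resolves to exactly one record
(property-tested).

The daily minimally required consumption is the exact inverse
`DMRC = target / content`, reported at full precision and half-up to
whole grams. Its inverse identity —
`meets_guideline(content, DMRC, target)` holds with supplied = target —
is an acceptance property (with a $10^{-12}$ epsilon absorbing binary
round-off at the boundary). All three EPA+DHA tiers (0.25, 0.5,
1.0 g/day) are always computed. The assumed ALA→EPA+DHA conversion is
15% by default (`ala_equivalent_epa_dha()`), a mid-range literature
value for healthy adults; the seafood serving behind the DGA guideline
defaults to 31.2 g/day (1.1 oz at the 28.35 g avoirdupois ounce — the
8 oz/week ÷ 7 arithmetic; some sources print 34.2 g, available via
`oz_grams`).

## Stratified intake and adequacy

`estimate_intake()` multiplies each stratum's consumption statistics
(mean, P50, P95 in g food/day) by the category-mean content and sums
over the contributing categories — ALA from edible oils and nuts/seeds,
EPA+DHA from fish, crustaceans and mollusks, no cross-contributions.
Three conventions matter:

- **Totals are statistic-wise sums of unrounded contributions.** The
  bundled published intake tables confirm this to within their printed
  0.001 g/day resolution (exactly, for the female ALA mean column), the
  residue implying the original summation happened before rounding.
- **A sum of per-category percentiles is an upper bound**, not the true
  percentile of the total; the published tables use this convention and
  so does the package, documented rather than corrected.
- **Adequacy is `statistic ≥ lower bound` of the recommendation** (the
  250 mg of WHO's 250–500 mg range), evaluated per statistic. On the
  bundled EPA+DHA table this rule reproduces every published adequacy
  marker cell for cell.
- A consumption stratum spanning several NIH age groups (e.g. 0–3
  years) is scored against the **oldest contained group** (0.7 g/day),
  a deterministic choice that is conservative for growth; the sources
  do not state their mapping.

A median-content pathway (`statistic = "median_content"`) exists for
sensitivity analysis but no published fixture exercises it.

## The synthetic consumption generator

The national consumption survey behind the bundled intake tables is not
publicly deposited, so `generate_consumption()` draws per-person daily
amounts from log-normal distributions per stratum × category and
summarises them with the nearest-rank percentile convention (platform
independent, unlike interpolating quantile types). Log-normal is the
standard right-skew model for food consumption, and matches the
published P50 ≪ mean < P95 pattern (roughly 1 : 4 : 14), reproduced by
the default log-scale sd of 1.7. `taiwan_consumption_spec()` sets seven
age strata, both sexes, five categories, adult medians of a few grams
of oil up to ~18 g of fish per day with age-scaled children's medians,
and 500 participants per stratum; these magnitudes are *illustrative*.
The generator emulates the survey's structure — skew, stratification,
seed-determinism — not its true distributions, sampling weights, or
within-person day-to-day correlation. A green synthetic test therefore
establishes that the pipeline's arithmetic and plumbing are correct
(degenerate inputs recover `content × amount` exactly; stochastic
stratum means converge to $c\,e^{\mu+\sigma^2/2}$ within 2% at
$n = 10^5$), not that the default magnitudes describe any real
population.

`generate_composition()` builds records whose scored bands follow a
requested mix in expectation, with fatty-acid profiles constructed to
be exactly consistent with the stored share, so both scoring routes can
be cross-checked on data with known truth.

## Degenerate inputs and numerical choices

- Zero fatty-acid sum makes the share undefined: an error, never NaN.
- Zero-content foods cannot meet any target: `minimal_required_consumption()`
  refuses them rather than returning infinity.
- Censored table cells (`< 0.01`) are loaded as their bound with a
  censoring flag; QC accepts any display strictly below the bound.
- Rounding epsilons: $10^{-9}$ inside `round_half_up()` (ties stored
  inexactly in binary), $10^{-12}$ relative in the guideline boundary.
- Loading rejects, row by row with diagnostics, records that fail
  coercion, leave `[0,1]` bounds, carry unknown categories (the
  five-way vocabulary is closed), or provide neither share nor profile;
  duplicated identifiers resolve in favour of the raw preparation.

## Known limitations

- Single-entry composition records: no variance, so no uncertainty
  intervals on intake — this is a deterministic screening estimate.
- 100% bioavailability and raw-food composition; cooking losses and
  matrix effects are out of scope.
- The published oil band percentages (22.7% high / 54.6% moderate)
  imply a 22-row denominator and a high-band rule excluding corn oil;
  no stated rule reproduces them, so the package reports its own
  consistent banding (6/23 high) and leaves the discrepancy to QC.
  Similarly the nuts/seeds "83.3% low" implies 18 rows where 19 are
  printed; the package reports 15/19.
- Supplements, meat, algae and vegetables are not modelled; intakes are
  lower bounds on total omega-3 exposure.
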