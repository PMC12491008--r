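#' Registry of recommended daily omega-3 intakes
#'
#' Seeds the authority recommendations used throughout the package:
#' the NIH adequate-intake values for ALA by life stage (0.32 g/day at
#' 0–6 months up to 1.6 / 1.1 g/day for adult men / women, with 1.4 and
#' 1.3 g/day in pregnancy and lactation) and the combined EPA+DHA
#' recommendations of the WHO and AHA (250–500 mg/day), EFSA (250 mg/day)
#' and the US Dietary Guidelines for Americans (about 250 mg/day via
#' 8 oz seafood per week). Age intervals are half-open and
#' lower-inclusive on the published group labels, so an exact boundary
#' age (13 y, 18 y) resolves to the younger stratum; infant groups are
#' expressed in fractional years (7–12 months is `[7/12, 1)`).
#'
#' @return A tibble with columns `nutrient` (`"ALA"` or `"EPA_DHA"`),
#'   `authority`, `sex` (`"male"`, `"female"`, `"any"`), `age_low`,
#'   `age_high` (years, half-open `[low, high)`), `life_stage` (`"none"`,
#'   `"pregnant"`, `"lactating"`), `amount_low`, `amount_high` (g/day).
#' @export
reference_intakes <- function() {
  nih <- tibble::tribble(
    ~sex,     ~age_low, ~age_high, ~life_stage,  ~amount_low,
    "any",    0,        7 / 12,    "none",       0.32,
    "any",    7 / 12,   1,         "none",       0.5,
    "any",    1,        4,         "none",       0.7,
    "any",    4,        9,         "none",       0.9,
    "male",   9,        14,        "none",       1.2,
    "female", 9,        14,        "none",       1.0,
    "male",   14,       19,        "none",       1.6,
    "female", 14,       19,        "none",       1.1,
    "male",   19,       121,       "none",       1.6,
    "female", 19,       121,       "none",       1.1,
    "female", 0,        121,       "pregnant",   1.4,
    "female", 0,        121,       "lactating",  1.3
  )
  nih$nutrient <- "ALA"
  nih$authority <- "NIH"
  nih$amount_high <- NA_real_

  epa_dha <- tibble::tribble(
    ~authority, ~amount_low, ~amount_high,
    "WHO",      0.25,        0.5,
    "AHA",      0.25,        0.5,
    "EFSA",     0.25,        NA_real_,
    "DGA",      0.25,        NA_real_
  )
  epa_dha$nutrient <- "EPA_DHA"
  epa_dha$sex <- "any"
  epa_dha$age_low <- 0
  epa_dha$age_high <- 121
  epa_dha$life_stage <- "none"

  cols <- c("nutrient", "authority", "sex", "age_low", "age_high",
            "life_stage", "amount_low", "amount_high")
  dplyr::bind_rows(nih[cols], epa_dha[cols])
}

#' Look up a recommended intake
#'
#' Resolves the unique recommendation for a nutrient, authority and
#' person. A pregnancy or lactation flag overrides the sex-by-age lookup.
#'
#' @param nutrient `"ALA"` or `"EPA_DHA"`.
#' @param authority One of `"NIH"`, `"WHO"`, `"AHA"`, `"EFSA"`, `"DGA"`.
#' @param sex `"male"`, `"female"` or `"any"`.
#' @param age Age in years (fractional for infants).
#' @param life_stage `"none"`, `"pregnant"` or `"lactating"`.
#' @param registry Registry tibble (default [reference_intakes()]).
#' @return A one-row tibble of the matching recommendation.
#' @examples
#' lookup_reference("ALA", "NIH", sex = "male", age = 30)
#' @export
lookup_reference <- function(nutrient, authority, sex = "any", age,
                             life_stage = "none",
                             registry = reference_intakes()) {
  nutrient <- match.arg(nutrient, c("ALA", "EPA_DHA"))
  authority <- match.arg(authority, c("NIH", "WHO", "AHA", "EFSA", "DGA"))
  life_stage <- match.arg(life_stage, c("none", "pregnant", "lactating"))
  assert_scalar_number(age, "age", lower = 0, upper = 120)
  hit <- registry[registry$nutrient == nutrient &
                    registry$authority == authority &
                    registry$life_stage == life_stage &
                    (registry$sex == "any" | registry$sex == sex) &
                    registry$age_low <= age & age < registry$age_high, ,
                  drop = FALSE]
  if (nrow(hit) == 0) {
    abort(sprintf(
      "no %s recommendation from %s for sex=%s, age=%s, life_stage=%s.",
      nutrient, authority, sex, format(age), life_stage))
  }
  if (nrow(hit) > 1) {
    abort(sprintf("ambiguous registry: %d records match (%s, %s, sex=%s, age=%s).",
                  nrow(hit), nutrient, authority, sex, format(age)))
  }
  hit
}

#' Daily minimally required consumption
#'
#' The grams of a food needed per day to supply a nutrient target:
#' `target / content_exact`. Also reported rounded half-up to the nearest
#' gram, the precision at which such requirements are usually
#' communicated.
#'
#' @param scored One or more scored foods ([score_content()]).
#' @param target Recommended daily amount, g/day.
#' @return A tibble `food_id`, `name`, `category`, `content_exact`,
#'   `target`, `grams_exact`, `grams_rounded`, ordered as the input.
#' @examples
#' oils <- score_content(bundled_composition("edible_oil"))
#' minimal_required_consumption(oils[oils$name == "Flaxseed oil", ], 1.6)
#' @export
minimal_required_consumption <- function(scored, target) {
  assert_scalar_number(target, "target", lower = 1e-12)
  if (any(is.na(scored$content_exact) | scored$content_exact <= 0)) {
    offenders <- scored$name[is.na(scored$content_exact) | scored$content_exact <= 0]
    abort(sprintf("food(s) with zero omega-3 content cannot meet any target: %s",
                  paste(head(offenders, 5), collapse = ", ")))
  }
  grams <- target / scored$content_exact
  tibble::tibble(
    food_id = scored$food_id, name = scored$name, category = scored$category,
    content_exact = scored$content_exact, target = target,
    grams_exact = grams, grams_rounded = round_half_up(grams, 0)
  )
}

#' EPA+DHA equivalent of an ALA intake
#'
#' Applies the assumed metabolic conversion of ingested ALA to long-chain
#' EPA+DHA (default 15%).
#'
#' @param ala_g ALA intake, g/day (non-negative).
#' @param conversion_rate Fraction converted, in `[0, 1]` (default 0.15).
#' @return EPA+DHA-equivalent g/day.
#' @examples
#' ala_equivalent_epa_dha(3.75) # about 0.56 g/day
#' @export
ala_equivalent_epa_dha <- function(ala_g, conversion_rate = 0.15) {
  if (any(ala_g < 0)) abort("`ala_g` must be non-negative.")
  assert_scalar_number(conversion_rate, "conversion_rate", 0, 1)
  ala_g * conversion_rate
}

#' Does a daily portion meet a guideline?
#'
#' Computes the nutrient supplied by eating `daily_grams` of each scored
#' food (`content_exact * daily_grams`) and flags whether it reaches the
#' target.
#'
#' @param scored Scored foods ([score_content()]).
#' @param daily_grams Daily portion, g/day (non-negative scalar or vector).
#' @param target Recommended daily amount, g/day.
#' @return A tibble `food_id`, `name`, `daily_grams`, `supplied`
#'   (g nutrient/day), `meets` (logical, `supplied >= target`).
#' @examples
#' fish <- score_content(bundled_composition("fish"))
#' # one standard 1.1 oz (31.2 g) serving against the 250 mg/day tier
#' summary(meets_guideline(fish, 31.2, 0.25)$meets)
#' @export
meets_guideline <- function(scored, daily_grams, target) {
  if (any(daily_grams < 0)) abort("`daily_grams` must be non-negative.")
  assert_scalar_number(target, "target", lower = 1e-12)
  supplied <- scored$content_exact * daily_grams
  # epsilon absorbs round-off so that eating exactly the minimal required
  # amount counts as meeting its own target
  tibble::tibble(food_id = scored$food_id, name = scored$name,
                 daily_grams = daily_grams, supplied = supplied,
                 meets = supplied >= target - 1e-12 * max(1, target))
}

#' Grams of seafood per serving
#'
#' Converts an ounce-denominated serving to grams. The 1.1 oz/day implied
#' by the 8 oz/week seafood guideline is 31.2 g at the standard 28.35 g
#' avoirdupois ounce; some sources print 34.2 g for the same serving, so
#' the factor is configurable.
#'
#' @param oz Ounces (default 1.1).
#' @param grams_per_oz Grams per ounce (default 28.35).
#' @return Grams.
#' @export
oz_to_grams <- function(oz = 1.1, grams_per_oz = 28.35) {
  round_half_up(oz * grams_per_oz, 1)
}
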