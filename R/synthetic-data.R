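#' Specify a synthetic consumption survey
#'
#' A consumption spec is one row per stratum (sex by age interval) and
#' food category, giving the log-normal parameters of per-person daily
#' consumption and the number of survey participants to draw. The
#' log-normal family mirrors the strong right skew of real food
#' consumption surveys, where the median sits far below the mean and the
#' P95 far above it.
#'
#' @param strata Tibble with columns `sex`, `age_low`, `age_high`,
#'   `body_weight` (kg).
#' @param categories Character vector of food categories.
#' @param meanlog,sdlog Log-scale location and scale. Either scalars,
#'   vectors along `categories`, or a function of `(stratum_row, category)`
#'   returning a scalar.
#' @param n Participants per stratum (scalar or vector along strata).
#' @return A `consumption_spec` tibble with one row per stratum by
#'   category: `sex`, `age_low`, `age_high`, `body_weight`, `category`,
#'   `meanlog`, `sdlog`, `n`.
#' @export
consumption_spec <- function(strata, categories = FOOD_CATEGORIES,
                             meanlog = 0, sdlog = 1, n = 500) {
  if (any(n < 1)) abort("sample size `n` must be at least 1 per stratum.")
  if (any(sdlog < 0)) abort("`sdlog` must be non-negative.")
  grid <- tidyr::expand_grid(strata, category = categories)
  pick <- function(par) {
    if (is.function(par)) {
      vapply(seq_len(nrow(grid)),
             function(i) par(grid[i, ], grid$category[i]), numeric(1))
    } else if (length(par) == length(categories)) {
      par[match(grid$category, categories)]
    } else {
      rep_len(par, nrow(grid))
    }
  }
  grid$meanlog <- pick(meanlog)
  grid$sdlog <- pick(sdlog)
  grid$n <- if (length(n) == nrow(strata)) {
    n[match(interaction(grid$sex, grid$age_low),
            interaction(strata$sex, strata$age_low))]
  } else rep_len(n, nrow(grid))
  class(grid) <- c("consumption_spec", class(grid))
  grid
}

#' Default Taiwan-like consumption spec
#'
#' Seven age strata (0–3, 3–6, 6–12, 12–16, 16–18, 19–65, over 65 years),
#' both sexes and the five food categories, with log-normal medians in
#' the magnitude range of published Taiwanese consumption statistics
#' (a few grams of cooking oil, tens of grams of fish per adult day) and
#' a common log-scale sd of 1.7, which reproduces the observed
#' P50-to-mean-to-P95 spread of roughly 1 : 4 : 14. Children's medians
#' are scaled down by age. All values are illustrative defaults, not a
#' reconstruction of the (undeposited) national survey.
#'
#' @param n Participants per stratum (default 500).
#' @return A `consumption_spec` tibble.
#' @export
taiwan_consumption_spec <- function(n = 500) {
  ages <- tibble::tibble(
    age_low = c(0, 3, 6, 12, 16, 19, 65),
    age_high = c(3, 6, 12, 16, 18, 65, 120),
    scale = c(0.25, 0.45, 0.65, 0.9, 1, 1, 0.85),
    bw_male = c(13, 19, 32, 52, 63, 68, 64),
    bw_female = c(12, 18, 31, 49, 54, 57, 55)
  )
  strata <- dplyr::bind_rows(
    tibble::tibble(sex = "male", age_low = ages$age_low,
                   age_high = ages$age_high, body_weight = ages$bw_male,
                   scale = ages$scale),
    tibble::tibble(sex = "female", age_low = ages$age_low,
                   age_high = ages$age_high, body_weight = ages$bw_female,
                   scale = ages$scale)
  )
  # Adult median daily consumption, g/day, by category.
  median_g <- c(edible_oil = 4, nut_seed = 12, fish = 18,
                crustacean = 2.5, mollusk = 1)
  spec <- consumption_spec(
    strata[c("sex", "age_low", "age_high", "body_weight")],
    categories = names(median_g),
    meanlog = function(stratum, category) {
      sc <- strata$scale[strata$sex == stratum$sex &
                           strata$age_low == stratum$age_low][1]
      log(median_g[[category]] * sc)
    },
    sdlog = 1.7, n = n
  )
  spec
}

nearest_rank <- function(x, p) {
  sort(x)[max(1L, ceiling(p * length(x)))]
}

#' Generate a synthetic consumption survey
#'
#' Draws iid per-person daily consumption amounts for every stratum and
#' category of the spec and summarises them into the consumption-table
#' schema (mean, empirical P50 and P95 by the nearest-rank convention).
#' The seed fully determines the output.
#'
#' @param spec A [consumption_spec()].
#' @param seed Integer random seed (default 1).
#' @return A list with `individuals` (tibble: `sex`, `age_low`,
#'   `age_high`, `category`, `person`, `amount`) and `strata` (tibble in
#'   the [read_consumption_table()] schema).
#' @examples
#' sim <- generate_consumption(taiwan_consumption_spec(n = 50), seed = 7)
#' head(sim$strata)
#' @export
generate_consumption <- function(spec, seed = 1) {
  if (!inherits(spec, "consumption_spec")) {
    abort("`spec` must be created by consumption_spec().")
  }
  withr::with_seed(seed, {
    draws <- lapply(seq_len(nrow(spec)), function(i) {
      amount <- rlnorm(spec$n[i], spec$meanlog[i], spec$sdlog[i])
      tibble::tibble(sex = spec$sex[i], age_low = spec$age_low[i],
                     age_high = spec$age_high[i],
                     category = spec$category[i],
                     person = seq_len(spec$n[i]), amount = amount)
    })
  })
  individuals <- dplyr::bind_rows(draws)
  strata <- tibble::tibble(
    sex = spec$sex, age_low = spec$age_low, age_high = spec$age_high,
    body_weight = spec$body_weight, category = spec$category,
    mean = vapply(draws, function(d) mean(d$amount), numeric(1)),
    p50 = vapply(draws, function(d) nearest_rank(d$amount, 0.50), numeric(1)),
    p95 = vapply(draws, function(d) nearest_rank(d$amount, 0.95), numeric(1))
  )
  list(individuals = individuals, strata = strata)
}

#' Generate a synthetic composition table
#'
#' Builds composition records whose scored content bands follow a
#' requested mix in expectation, emulating the structure of reference
#' composition tables (including the low-content majority typical of
#' aquatic foods). Each record carries a fat fraction, an omega-3
#' share of fat, and a full fatty-acid profile constructed to be exactly
#' consistent with that share.
#'
#' @param n_per_category Named integer vector, records per category.
#' @param band_mix Named fractions over `c("low", "moderate", "high")`
#'   summing to 1.
#' @param seed Integer random seed (default 1).
#' @param fat_cap Maximum fat fraction of generated foods (default 1).
#'   Requesting moderate or high bands under a cap too small to reach
#'   them is a spec error.
#' @return A tibble of composition records as from
#'   [load_composition_table()].
#' @examples
#' gen <- generate_composition(c(fish = 20), c(low = 0.5, moderate = 0.3, high = 0.2))
#' table(score_content(gen)$band)
#' @export
generate_composition <- function(n_per_category,
                                 band_mix = c(low = 0.7, moderate = 0.2, high = 0.1),
                                 seed = 1, fat_cap = 1) {
  if (is.null(names(n_per_category)) ||
      !all(names(n_per_category) %in% FOOD_CATEGORIES)) {
    abort("`n_per_category` must be named with food categories.")
  }
  mix <- setNames(rep(0, 3), band_levels)
  mix[names(band_mix)] <- band_mix
  if (abs(sum(mix) - 1) > 1e-9) abort("`band_mix` must sum to 1.")
  assert_scalar_number(fat_cap, "fat_cap", lower = 1e-4, upper = 1)
  # Exact content ranges whose half-up display lands in each band.
  ranges <- list(low = c(2e-4, 0.00495), moderate = c(0.0051, 0.0249),
                 high = c(0.0251, min(0.45, 0.9 * fat_cap)))
  if (mix[["high"]] > 0 && ranges$high[2] <= ranges$high[1]) {
    abort("infeasible band mix: the high band is unreachable under `fat_cap`.")
  }
  if (mix[["moderate"]] > 0 && fat_cap < 0.0051) {
    abort("infeasible band mix: the moderate band is unreachable under `fat_cap`.")
  }
  total <- sum(n_per_category)
  withr::with_seed(seed, {
    category <- rep(names(n_per_category), n_per_category)
    band <- sample(band_levels, total, replace = TRUE, prob = mix)
    content <- vapply(band, function(b) runif(1, ranges[[b]][1], ranges[[b]][2]),
                      numeric(1), USE.NAMES = FALSE)
    share <- runif(total, pmin(pmax(content / fat_cap, 0.05), 0.9), 0.95)
    fat <- content / share
    # Profile per 100 g food; identified fatty acids at 95% of fat.
    fa_sum <- fat * 100 * 0.95
    o3 <- share * fa_sum
    plant <- category %in% c("edible_oil", "nut_seed")
    ala <- ifelse(plant, o3, 0.05 * o3)
    epa <- ifelse(plant, 0, 0.40 * o3)
    dha <- o3 - ala - epa
    other_pufa <- runif(total, 0, 0.3) * (fa_sum - o3)
    pufa <- o3 + other_pufa
    sfa_frac <- runif(total, 0.3, 0.7)
    sfa <- sfa_frac * (fa_sum - pufa)
    mufa <- fa_sum - pufa - sfa
  })
  tibble::tibble(
    food_id = sprintf("syn_%s_%03d", category,
                      unlist(lapply(n_per_category, seq_len))),
    name = sprintf("synthetic %s %03d", category,
                   unlist(lapply(n_per_category, seq_len))),
    species_binomial = NA_character_,
    category = category, preparation = "raw",
    fat_fraction = fat, omega3_share_of_fat = share, share_censored = FALSE,
    ala = ala, epa = epa, dha = dha,
    sfa_total = sfa, mufa_total = mufa, pufa_total = pufa,
    listed_content = NA_real_, listed_censored = FALSE
  )
}
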