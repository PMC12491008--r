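#' Omega-3 share of total fatty acids
#'
#' The fraction of a food's identified fatty acids that is omega-3,
#' computed from a per-100 g profile as
#' `(ala + epa + dha) / (sfa + mufa + pufa)`.
#'
#' @param ala,epa,dha Omega-3 fatty-acid masses, g per 100 g food.
#' @param sfa,mufa,pufa Total saturated, monounsaturated and
#'   polyunsaturated fatty-acid masses, g per 100 g food. The three
#'   omega-3 acids are counted inside `pufa`.
#' @param epa_dha_only If `TRUE`, the numerator is `epa + dha` alone
#'   (strict long-chain scoring for marine recommendations).
#' @return Fraction in `[0, 1]`; errors if the fatty-acid sum is not
#'   positive.
#' @examples
#' omega3_share(ala = 10, epa = 0, dha = 0, sfa = 40, mufa = 30, pufa = 30)
#' @export
omega3_share <- function(ala, epa, dha, sfa, mufa, pufa,
                         epa_dha_only = FALSE) {
  denom <- sfa + mufa + pufa
  if (any(is.na(denom)) || any(denom <= 0)) {
    abort("undefined omega-3 share: fatty-acid sum (sfa + mufa + pufa) must be positive.")
  }
  num <- if (epa_dha_only) epa + dha else ala + epa + dha
  if (any(num < 0)) abort("fatty-acid masses must be non-negative.")
  num / denom
}

band_levels <- c("low", "moderate", "high")

# Band is a pure function of the 2-decimal display value:
# low < 0.01, moderate 0.01-0.02, high > 0.02 g/g.
band_of_display <- function(display) {
  cents <- display_cents(display)
  factor(ifelse(cents < 1L, "low", ifelse(cents <= 2L, "moderate", "high")),
         levels = band_levels)
}

#' Score the omega-3 content of foods
#'
#' Computes each record's omega-3 content in g per g food as
#' share-of-fat times fat fraction, where the share is taken from the
#' record directly or derived from its fatty-acid profile via
#' [omega3_share()]. The exact content is display-rounded half-up to two
#' decimals and classified into the low / moderate / high band.
#'
#' @param records Composition records ([load_composition_table()]).
#' @param epa_dha_only If `TRUE`, score only EPA+DHA; every record must
#'   then carry a fatty-acid profile.
#' @return A tibble: `food_id`, `name`, `category`, `content_exact`,
#'   `content_display`, `band`.
#' @examples
#' oils <- bundled_composition("edible_oil")
#' head(score_content(oils), 3)
#' @export
score_content <- function(records, epa_dha_only = FALSE) {
  n <- nrow(records)
  has_profile <- !is.na(records$ala) & !is.na(records$epa) & !is.na(records$dha) &
    !is.na(records$sfa_total) & !is.na(records$mufa_total) & !is.na(records$pufa_total)
  share <- rep(NA_real_, n)
  if (epa_dha_only) {
    if (any(!has_profile)) {
      abort(sprintf(
        "EPA+DHA-only scoring needs a fatty-acid profile; missing for: %s",
        paste(head(records$name[!has_profile], 5), collapse = ", ")))
    }
  } else {
    share <- records$omega3_share_of_fat
  }
  derive <- is.na(share) & has_profile
  if (any(derive)) {
    share[derive] <- omega3_share(
      records$ala[derive], records$epa[derive], records$dha[derive],
      records$sfa_total[derive], records$mufa_total[derive],
      records$pufa_total[derive], epa_dha_only = epa_dha_only)
  }
  if (any(is.na(share))) {
    abort(sprintf("no omega-3 share available for: %s",
                  paste(head(records$name[is.na(share)], 5), collapse = ", ")))
  }
  exact <- share * records$fat_fraction
  display <- round_half_up(exact, 2)
  tibble::tibble(
    food_id = records$food_id,
    name = records$name,
    category = records$category,
    content_exact = exact,
    content_display = display,
    band = band_of_display(display)
  )
}

#' Rank foods by omega-3 content
#'
#' Orders scored foods by descending exact content; ties are broken by
#' ascending name so the ordering is deterministic.
#'
#' @param scored Output of [score_content()].
#' @param top_n Maximum number of foods to return (default all).
#' @return The top `min(top_n, nrow(scored))` rows, with a `rank` column.
#' @export
rank_by_content <- function(scored, top_n = nrow(scored)) {
  if (nrow(scored) == 0) abort("cannot rank an empty collection.")
  assert_scalar_number(top_n, "top_n", lower = 1)
  out <- dplyr::arrange(scored, dplyr::desc(.data$content_exact), .data$name)
  out <- head(out, top_n)
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "rank")
}

#' Distribution of foods across content bands
#'
#' Counts and fractions of scored foods per content band (low < 0.01,
#' moderate 0.01–0.02, high > 0.02 g/g on the display value), overall or
#' within one category.
#'
#' @param scored Output of [score_content()].
#' @param category Optional single category to restrict to.
#' @return A tibble with one row per band: `category`, `band`, `count`,
#'   `fraction`. Fractions sum to 1.
#' @examples
#' band_distribution(score_content(bundled_composition("crustacean")))
#' @export
band_distribution <- function(scored, category = NULL) {
  if (!is.null(category)) {
    scored <- scored[scored$category == category, , drop = FALSE]
  }
  if (nrow(scored) == 0) {
    abort("no scored records in the requested category.")
  }
  counts <- table(factor(scored$band, levels = band_levels))
  tibble::tibble(
    category = if (is.null(category)) "all" else category,
    band = factor(band_levels, levels = band_levels),
    count = as.integer(counts),
    fraction = as.integer(counts) / nrow(scored)
  )
}
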