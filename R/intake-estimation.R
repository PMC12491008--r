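#' Read a stratified consumption table
#'
#' Loads sex-by-age-by-category consumption statistics from delimited
#' text with columns `sex`, `age_low`, `age_high`, `body_weight`,
#' `category`, `mean`, `p50`, `p95` (g food/day; body weight in kg is
#' carried as metadata and never enters the intake arithmetic).
#'
#' @param path Delimited text file (tab or comma separated).
#' @param sep Field separator (default tab).
#' @return A tibble of consumption strata.
#' @export
read_consumption_table <- function(path, sep = "\t") {
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    fileEncoding = "UTF-8")
  needed <- c("sex", "age_low", "age_high", "body_weight", "category",
              "mean", "p50", "p95")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("consumption table is missing column(s): %s",
                  paste0("'", missing_cols, "'", collapse = ", ")))
  }
  out <- tibble::as_tibble(raw[needed])
  if (any(out$mean < 0 | out$p50 < 0 | out$p95 < 0, na.rm = TRUE)) {
    abort("consumption statistics must be non-negative.")
  }
  if (any(out$p50 > out$p95 + 1e-9, na.rm = TRUE)) {
    abort("consumption p50 must not exceed p95 within a stratum/category.")
  }
  out
}

#' Mean omega-3 content per food category
#'
#' Arithmetic mean (and median) of the exact contents of the scored
#' records in each category. These category means are the concentration
#' term of the concentration-times-consumption intake model.
#'
#' @param scored Scored foods ([score_content()]).
#' @param categories Optional subset of categories; default all present.
#' @return A tibble `category`, `n`, `mean_content`, `median_content`.
#' @examples
#' category_mean_content(score_content(bundled_composition()))
#' @export
category_mean_content <- function(scored, categories = NULL) {
  if (!is.null(categories)) {
    scored <- scored[scored$category %in% categories, , drop = FALSE]
    gone <- setdiff(categories, scored$category)
    if (length(gone) > 0) {
      abort(sprintf("no scored records in category: %s",
                    paste(gone, collapse = ", ")))
    }
  }
  if (nrow(scored) == 0) abort("no scored records to average.")
  out <- dplyr::summarise(
    dplyr::group_by(scored, .data$category),
    n = dplyr::n(),
    mean_content = mean(.data$content_exact),
    median_content = median(.data$content_exact),
    .groups = "drop"
  )
  out[order(match(out$category, FOOD_CATEGORIES)), , drop = FALSE]
}

#' Estimate stratified daily omega-3 intake
#'
#' Point-estimate exposure model: for every stratum and contributing food
#' category, intake statistic = consumption statistic (g food/day) times
#' the category's content (g omega-3/g food), assuming 100%
#' bioavailability. ALA is fed by the plant categories (edible oils,
#' nuts/seeds); EPA+DHA by the aquatic categories (fish, crustaceans,
#' mollusks). Cross-contributions are excluded. Per-stratum totals
#' (`category = "all_foods"`) are statistic-wise sums of the unrounded
#' contributions; note that a sum of per-category percentiles is an
#' upper-bound convention for the total's percentile, not its true value.
#'
#' @param consumption Consumption strata ([read_consumption_table()] or
#'   [generate_consumption()]`$strata`).
#' @param contents Named numeric vector of g/g contents per category, or
#'   the tibble from [category_mean_content()] (its `mean_content` is
#'   used; set `statistic = "median_content"` for median contents).
#' @param nutrient `"ALA"` or `"EPA_DHA"`.
#' @param statistic Which content column to use when `contents` is a
#'   tibble (default `"mean_content"`).
#' @return A tibble `sex`, `age_low`, `age_high`, `nutrient`, `category`,
#'   `mean`, `p50`, `p95` (g nutrient/day), with an `"all_foods"` total
#'   row per stratum.
#' @export
estimate_intake <- function(consumption, contents,
                            nutrient = c("ALA", "EPA_DHA"),
                            statistic = c("mean_content", "median_content")) {
  nutrient <- match.arg(nutrient)
  statistic <- match.arg(statistic)
  if (is.data.frame(contents)) {
    contents <- setNames(contents[[statistic]], contents$category)
  }
  cats <- NUTRIENT_CATEGORIES[[nutrient]]
  cons <- consumption[consumption$category %in% cats, , drop = FALSE]
  if (nrow(cons) == 0) {
    abort(sprintf("consumption table has no rows in the %s categories (%s).",
                  nutrient, paste(cats, collapse = ", ")))
  }
  consumed <- unique(cons$category)
  unmapped <- setdiff(consumed, names(contents)[!is.na(contents)])
  if (length(unmapped) > 0) {
    abort(sprintf("no content supplied for consumed category: %s",
                  paste(unmapped, collapse = ", ")))
  }
  cc <- unname(contents[cons$category])
  contrib <- tibble::tibble(
    sex = cons$sex, age_low = cons$age_low, age_high = cons$age_high,
    nutrient = nutrient, category = cons$category,
    mean = cons$mean * cc, p50 = cons$p50 * cc, p95 = cons$p95 * cc
  )
  totals <- dplyr::summarise(
    dplyr::group_by(contrib, .data$sex, .data$age_low, .data$age_high,
                    .data$nutrient),
    category = "all_foods",
    mean = sum(.data$mean), p50 = sum(.data$p50), p95 = sum(.data$p95),
    .groups = "drop"
  )
  out <- dplyr::bind_rows(contrib, totals)
  dplyr::arrange(out, .data$sex, .data$age_low,
                 match(.data$category, c(FOOD_CATEGORIES, "all_foods")))
}

# The reference for a consumption stratum spanning several NIH age groups
# is taken from the oldest contained group (deterministic, conservative
# for growth): probe just below the stratum's upper age bound.
stratum_reference <- function(nutrient, authority, sex, age_low, age_high,
                              registry = reference_intakes()) {
  probe <- min(age_high, 120) - 1e-6
  lookup_reference(nutrient, authority, sex = sex, age = probe,
                   registry = registry)
}

#' Flag adequacy of estimated intakes
#'
#' Compares every intake statistic (mean, P50, P95) of an estimate
#' against the applicable recommendation and flags it adequate when the
#' statistic is greater than or equal to the recommendation's lower
#' amount (the 250 mg of a 250–500 mg EPA+DHA range; the sex- and
#' age-specific NIH value for ALA, resolved per stratum from the oldest
#' contained age group).
#'
#' @param estimate Output of [estimate_intake()].
#' @param authority Authority whose recommendation to test against
#'   (default `"NIH"` for ALA, `"WHO"` for EPA+DHA).
#' @param registry Recommendation registry (default [reference_intakes()]).
#' @return `estimate` with columns `reference` (g/day) and logical
#'   `mean_adequate`, `p50_adequate`, `p95_adequate`.
#' @export
assess_adequacy <- function(estimate, authority = NULL,
                            registry = reference_intakes()) {
  nutrient <- unique(estimate$nutrient)
  if (length(nutrient) != 1) {
    abort("`estimate` must concern a single nutrient.")
  }
  authority <- authority %||% if (nutrient == "ALA") "NIH" else "WHO"
  if (!any(registry$nutrient == nutrient & registry$authority == authority)) {
    abort(sprintf("authority %s issues no %s recommendation.", authority,
                  nutrient))
  }
  strata <- unique(estimate[c("sex", "age_low", "age_high")])
  strata$reference <- vapply(seq_len(nrow(strata)), function(i) {
    stratum_reference(nutrient, authority, strata$sex[i], strata$age_low[i],
                      strata$age_high[i], registry)$amount_low
  }, numeric(1))
  out <- dplyr::left_join(estimate, strata,
                          by = c("sex", "age_low", "age_high"))
  out$mean_adequate <- out$mean >= out$reference
  out$p50_adequate <- out$p50 >= out$reference
  out$p95_adequate <- out$p95 >= out$reference
  out
}

#' Bundled stratified intake reference tables
#'
#' Published ALA and EPA+DHA daily intake estimates for the Taiwanese
#' population (sex by seven age strata by contributing food category plus
#' an all-foods total, each as mean/P50/P95 g/day), including the
#' original adequacy markers as 0/1 flag columns. Used as a consistency
#' fixture for the aggregation and adequacy logic; the underlying
#' individual-level consumption survey is not publicly deposited.
#'
#' @param nutrient `"ALA"` or `"EPA_DHA"`.
#' @return A tibble `sex`, `age_low`, `age_high`, `category`, `mean`,
#'   `p50`, `p95`, `mean_flag`, `p50_flag`, `p95_flag`.
#' @export
bundled_intake <- function(nutrient = c("ALA", "EPA_DHA")) {
  nutrient <- match.arg(nutrient)
  file <- if (nutrient == "ALA") "ala_intake_taiwan.tsv" else "epa_dha_intake_taiwan.tsv"
  path <- system.file("extdata", file, package = "omega3intake",
                      mustWork = TRUE)
  tibble::as_tibble(read.delim(path, sep = "\t", header = TRUE,
                               fileEncoding = "UTF-8"))
}
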