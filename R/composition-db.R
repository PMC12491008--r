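#' Describe the column layout of a composition table
#'
#' A dialect maps the columns of a delimited source file onto the fields
#' of a food composition record and declares which columns carry percent
#' values (converted to fractions on load, so a printed `57.7` becomes
#' `0.577`). Either a share-of-fat column or a full six-column fatty-acid
#' profile (per 100 g food) must be mapped.
#'
#' @param name Column holding the food name (mandatory).
#' @param fat Column holding total fat content (mandatory).
#' @param food_id Optional column holding a stable identifier; when absent
#'   identifiers are generated from the category and row number.
#' @param species Optional column with the species binomial.
#' @param category Optional column with the food category; alternatively
#'   fix the whole table's category with `category_value`.
#' @param category_value Fixed category for every row (one of
#'   `r paste0('"', FOOD_CATEGORIES, '"', collapse = ", ")`).
#' @param category_map Optional named character vector translating source
#'   labels to the closed category vocabulary. Unknown labels reject the
#'   row, they are never coerced.
#' @param preparation Optional column with the preparation state;
#'   `preparation_value` is used for rows (or tables) without one.
#' @param preparation_value Default preparation (default `"unknown"`).
#' @param share Optional column: omega-3 share of total fatty acids.
#' @param listed_content Optional column: the source's own omega-3 content
#'   (g/g), kept for quality control; censored entries such as `"< 0.01"`
#'   are parsed as an upper bound.
#' @param ala,epa,dha,sfa,mufa,pufa Optional columns of the fatty-acid
#'   profile in g per 100 g food; all six must be mapped together.
#' @param percent Character vector of mapped source columns whose values
#'   are percents.
#' @param sep Field separator (default tab).
#' @return A `composition_dialect` list, for [load_composition_table()].
#' @export
composition_dialect <- function(name = "name",
                                fat = "fat_pct",
                                food_id = NULL,
                                species = NULL,
                                category = NULL,
                                category_value = NULL,
                                category_map = NULL,
                                preparation = NULL,
                                preparation_value = "unknown",
                                share = NULL,
                                listed_content = NULL,
                                ala = NULL, epa = NULL, dha = NULL,
                                sfa = NULL, mufa = NULL, pufa = NULL,
                                percent = character(),
                                sep = "\t") {
  profile_cols <- c(ala = ala, epa = epa, dha = dha,
                    sfa = sfa, mufa = mufa, pufa = pufa)
  n_profile <- length(profile_cols)
  if (n_profile > 0 && n_profile < 6) {
    abort("a fatty-acid profile dialect must map all six of ala, epa, dha, sfa, mufa, pufa.")
  }
  if (is.null(share) && n_profile == 0) {
    abort("dialect must map `share` or a full fatty-acid profile.")
  }
  if (is.null(category) && is.null(category_value)) {
    abort("dialect must give `category` (column) or `category_value`.")
  }
  if (!is.null(category_value) && !category_value %in% FOOD_CATEGORIES) {
    abort(sprintf("unknown `category_value` \"%s\".", category_value))
  }
  if (!preparation_value %in% PREPARATIONS) {
    abort(sprintf("unknown `preparation_value` \"%s\".", preparation_value))
  }
  structure(
    list(name = name, fat = fat, food_id = food_id, species = species,
         category = category, category_value = category_value,
         category_map = category_map,
         preparation = preparation, preparation_value = preparation_value,
         share = share, listed_content = listed_content,
         profile = if (n_profile == 6) profile_cols,
         percent = percent, sep = sep),
    class = "composition_dialect"
  )
}

# Parse a numeric column that may contain censored entries like "< 0.01".
# Returns value (the bound for censored cells) plus a censored flag.
parse_censored_numeric <- function(x) {
  x <- trimws(x)
  censored <- grepl("^<", x)
  raw <- sub("^<\\s*", "", x)
  raw[raw == "" | is.na(x)] <- NA
  value <- suppressWarnings(as.numeric(raw))
  list(value = value, censored = censored & !is.na(value),
       bad = !is.na(raw) & is.na(value))
}

#' Load a food composition table
#'
#' Reads a delimited text file of per-food fat and fatty-acid data into a
#' tibble of composition records. Percent-valued columns declared by the
#' dialect are converted to fractions, so every internal quantity is a
#' dimensionless fraction in `[0, 1]` (fat per g food, omega-3 share of
#' fatty acids). Rows that cannot be coerced, carry an unknown category,
#' violate a record invariant, or provide neither a share nor a profile
#' are rejected with row-level diagnostics (attached as the `"rejected"`
#' attribute and reported via a warning); valid rows keep their source
#' order. When several rows share a `food_id`, the raw-preparation record
#' wins over processed duplicates.
#'
#' @param source Path (or connection) to a delimited text file with a
#'   header row.
#' @param dialect A [composition_dialect()] describing the columns.
#' @return A tibble with columns `food_id`, `name`, `species_binomial`,
#'   `category`, `preparation`, `fat_fraction`, `omega3_share_of_fat`,
#'   `share_censored`, `ala`, `epa`, `dha`, `sfa_total`, `mufa_total`,
#'   `pufa_total`, `listed_content`, `listed_censored`.
#' @export
load_composition_table <- function(source, dialect = composition_dialect()) {
  if (!inherits(dialect, "composition_dialect")) {
    abort("`dialect` must be created by composition_dialect().")
  }
  raw <- read.delim(source, sep = dialect$sep, header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    strip.white = TRUE, fileEncoding = "UTF-8")
  mandatory <- c(dialect$name, dialect$fat, dialect$category,
                 dialect$share, unname(dialect$profile))
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("composition source is missing mandatory column(s): %s",
                  paste0("'", missing_cols, "'", collapse = ", ")))
  }

  n <- nrow(raw)
  col_or <- function(col, default = NA_character_) {
    if (!is.null(col) && col %in% names(raw)) {
      x <- raw[[col]]
      x[x == ""] <- NA
      x
    } else rep(default, n)
  }
  as_fraction <- function(col) {
    p <- parse_censored_numeric(col_or(col))
    if (!is.null(col) && col %in% dialect$percent) p$value <- p$value / 100
    p
  }

  fat <- as_fraction(dialect$fat)
  share <- if (!is.null(dialect$share)) as_fraction(dialect$share)
  listed <- if (!is.null(dialect$listed_content)) as_fraction(dialect$listed_content)
  profile <- if (!is.null(dialect$profile)) {
    lapply(dialect$profile, function(col) as_fraction(col))
  }

  category <- if (!is.null(dialect$category_value)) {
    rep(dialect$category_value, n)
  } else {
    src <- col_or(dialect$category)
    if (!is.null(dialect$category_map)) {
      mapped <- unname(dialect$category_map[src])
      mapped[is.na(mapped) & src %in% FOOD_CATEGORIES] <- src[is.na(mapped) & src %in% FOOD_CATEGORIES]
      mapped
    } else src
  }
  preparation <- col_or(dialect$preparation, dialect$preparation_value)
  preparation[is.na(preparation) | preparation == ""] <- dialect$preparation_value

  records <- tibble::tibble(
    food_id = col_or(dialect$food_id),
    name = col_or(dialect$name),
    species_binomial = col_or(dialect$species),
    category = category,
    preparation = preparation,
    fat_fraction = fat$value,
    omega3_share_of_fat = if (is.null(share)) NA_real_ else share$value,
    share_censored = if (is.null(share)) FALSE else share$censored,
    ala = if (is.null(profile)) NA_real_ else profile$ala$value,
    epa = if (is.null(profile)) NA_real_ else profile$epa$value,
    dha = if (is.null(profile)) NA_real_ else profile$dha$value,
    sfa_total = if (is.null(profile)) NA_real_ else profile$sfa$value,
    mufa_total = if (is.null(profile)) NA_real_ else profile$mufa$value,
    pufa_total = if (is.null(profile)) NA_real_ else profile$pufa$value,
    listed_content = if (is.null(listed)) NA_real_ else listed$value,
    listed_censored = if (is.null(listed)) FALSE else listed$censored
  )
  if (all(is.na(records$food_id))) {
    records$food_id <- sprintf("%s_%03d", records$category, seq_len(n))
  }

  # Row-level validation; offenders are collected, not fatal.
  reason <- rep(NA_character_, n)
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- msg
  }
  has_profile <- !is.na(records$ala) & !is.na(records$epa) & !is.na(records$dha) &
    !is.na(records$sfa_total) & !is.na(records$mufa_total) & !is.na(records$pufa_total)
  flag(is.na(records$name) | records$name == "", "missing food name")
  flag(!records$category %in% FOOD_CATEGORIES,
       "unknown category (not in the closed five-way vocabulary)")
  flag(!records$preparation %in% PREPARATIONS, "unknown preparation")
  flag(is.na(records$fat_fraction), "fat content failed numeric coercion")
  flag(records$fat_fraction < 0 | records$fat_fraction > 1,
       "fat_fraction outside [0, 1]")
  flag(is.na(records$omega3_share_of_fat) & !has_profile,
       "neither omega-3 share nor full fatty-acid profile")
  flag(!is.na(records$omega3_share_of_fat) &
         (records$omega3_share_of_fat < 0 | records$omega3_share_of_fat > 1),
       "omega3_share_of_fat outside [0, 1]")
  fa_sum <- records$sfa_total + records$mufa_total + records$pufa_total
  o3_sum <- records$ala + records$epa + records$dha
  flag(has_profile & fa_sum <= 0, "fatty-acid profile sums to zero")
  flag(has_profile & (records$ala < 0 | records$epa < 0 | records$dha < 0 |
                        records$sfa_total < 0 | records$mufa_total < 0 |
                        records$pufa_total < 0),
       "negative fatty-acid mass")
  flag(has_profile & o3_sum > records$pufa_total * (1 + 1e-9),
       "ala+epa+dha exceeds pufa_total")

  bad <- !is.na(reason)
  rejected <- tibble::tibble(row = which(bad), name = records$name[bad],
                             reason = reason[bad])
  records <- records[!bad, , drop = FALSE]

  # Duplicate identifiers: the raw record wins over processed variants.
  if (anyDuplicated(records$food_id)) {
    ord <- order(match(records$food_id, unique(records$food_id)),
                 records$preparation != "raw")
    records <- records[ord, , drop = FALSE]
    records <- records[!duplicated(records$food_id), , drop = FALSE]
  }

  if (nrow(rejected) > 0) {
    warn(sprintf("%d row(s) rejected while loading composition table: %s",
                 nrow(rejected),
                 paste(sprintf("row %d (%s)", rejected$row, rejected$reason),
                       collapse = "; ")))
  }
  attr(records, "rejected") <- rejected
  records
}

# Dialect understood by write_composition_table()'s output.
canonical_dialect <- function() {
  composition_dialect(
    name = "name", fat = "fat_fraction", food_id = "food_id",
    species = "species_binomial", category = "category",
    preparation = "preparation",
    share = "omega3_share_of_fat", listed_content = "listed_content",
    ala = "ala", epa = "epa", dha = "dha",
    sfa = "sfa_total", mufa = "mufa_total", pufa = "pufa_total"
  )
}

#' Write composition records as delimited text
#'
#' Writes the canonical tab-separated layout; censored listed contents are
#' written back in their `"<bound"` form so that a write/load round trip
#' reproduces the records field for field (see [canonical_dialect()]).
#'
#' @param records Tibble from [load_composition_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(records, path) {
  out <- records
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 15, trim = TRUE,
                                                 scientific = FALSE))
  num_cols <- c("fat_fraction", "omega3_share_of_fat", "ala", "epa", "dha",
                "sfa_total", "mufa_total", "pufa_total", "listed_content")
  for (col in num_cols) out[[col]] <- fmt(out[[col]])
  out$listed_content <- ifelse(records$listed_censored & !is.na(records$listed_content),
                               paste0("<", out$listed_content), out$listed_content)
  out$omega3_share_of_fat <- ifelse(records$share_censored & !is.na(records$omega3_share_of_fat),
                                    paste0("<", out$omega3_share_of_fat),
                                    out$omega3_share_of_fat)
  out$share_censored <- NULL
  out$listed_censored <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

bundled_files <- c(
  edible_oil = "edible_oils.tsv",
  nut_seed = "nuts_seeds.tsv",
  fish = "fish.tsv",
  crustacean = "crustaceans.tsv",
  mollusk = "mollusks.tsv"
)

bundled_dialect <- function(category) {
  composition_dialect(
    name = "name", fat = "fat_pct",
    species = if (category %in% c("fish", "crustacean", "mollusk")) "species",
    category_value = category,
    preparation = if (category == "nut_seed") "preparation",
    preparation_value = "raw",
    share = "omega3_pct_fat", listed_content = "omega3_g_per_g",
    percent = c("omega3_pct_fat", "fat_pct")
  )
}

#' Bundled reference composition tables
#'
#' Returns the package's bundled food composition records, compiled from
#' the Taiwan FDA Food Nutrient Database listings for edible oils, nuts
#' and seeds, fish, crustaceans and mollusks (raw foods; nuts pretreated
#' as commonly consumed). Each record carries the share of total fatty
#' acids that is omega-3, the fat fraction, and the source's own listed
#' omega-3 content for quality control.
#'
#' @param categories Categories to load (default: all five).
#' @return A tibble of composition records, see [load_composition_table()].
#' @examples
#' oils <- bundled_composition("edible_oil")
#' nrow(oils)
#' @export
bundled_composition <- function(categories = FOOD_CATEGORIES) {
  categories <- match.arg(categories, FOOD_CATEGORIES, several.ok = TRUE)
  parts <- lapply(categories, function(cat) {
    path <- system.file("extdata", bundled_files[[cat]],
                        package = "omega3intake", mustWork = TRUE)
    load_composition_table(path, bundled_dialect(cat))
  })
  records <- dplyr::bind_rows(parts)
  notes <- NULL
  if ("edible_oil" %in% categories) {
    # The source text reports n = 22 oils, but 23 rows are listed; the
    # discrepancy is surfaced by validate_and_qc() rather than resolved.
    notes <- tibble::tibble(
      food_id = NA_character_, name = "edible oils",
      field_name = "row_count", listed_value = 22, recomputed_value = 23,
      severity = "info",
      note = "source narrative reports 22 edible oils; 23 rows are listed"
    )
  }
  attr(records, "qc_notes") <- notes
  attr(records, "rejected") <- NULL
  records
}

#' Quality-check listed omega-3 contents against recomputation
#'
#' For every record with a listed content value, recomputes the omega-3
#' content from the share-of-fat and fat columns via [score_content()] and
#' compares the display-rounded result against the listed value. A
#' `mismatch` finding is emitted when the recomputed display value differs
#' beyond the rounding tolerance of the listed precision (a 2-decimal
#' listed value matches iff the exact value half-up-rounds to it; a
#' censored listed bound such as `<0.01` matches iff the display value is
#' below the bound). `info` findings mark boundary roundings, where the
#' exact content lies within half a display unit (0.0005 g/g) of a
#' rounding cut point, plus any source-level notes attached to the
#' records. QC never aborts and is deterministic: identical inputs give
#' identical findings in identical order.
#'
#' @param records Composition records.
#' @param listed_contents Optional numeric vector of listed g/g values
#'   aligned with `records`; defaults to the records' `listed_content`.
#' @param digits Decimal precision of the listed values (default 2).
#' @return A tibble of findings: `food_id`, `name`, `field_name`,
#'   `listed_value`, `recomputed_value`, `severity`, `note`.
#' @export
validate_and_qc <- function(records, listed_contents = NULL, digits = 2) {
  listed <- listed_contents %||% records$listed_content
  censored <- if (is.null(listed_contents)) records$listed_censored else
    rep(FALSE, length(listed))
  scored <- score_content(records)
  display <- round_half_up(scored$content_exact, digits)

  finding <- function(i, field, lv, rv, severity, note) {
    tibble::tibble(food_id = records$food_id[i], name = records$name[i],
                   field_name = field, listed_value = lv,
                   recomputed_value = rv, severity = severity, note = note)
  }
  out <- list()
  cuts <- c(0.005, 0.015, 0.025)
  half_ulp <- 0.5 / 10^digits / 10  # 0.0005 at 2-decimal display
  for (i in seq_len(nrow(records))) {
    if (!is.na(listed[i])) {
      ok <- if (censored[i]) {
        display[i] < listed[i] - 1e-9
      } else {
        abs(display[i] - listed[i]) < 0.5 / 10^digits - 1e-9
      }
      if (!ok) {
        out[[length(out) + 1L]] <- finding(
          i, "omega3_g_per_g", listed[i], display[i], "mismatch",
          sprintf("listed %s but share x fat recomputes to %.6f (display %s)",
                  if (censored[i]) paste0("<", listed[i]) else format(listed[i]),
                  scored$content_exact[i], format(display[i])))
      }
    }
    near <- cuts[abs(scored$content_exact[i] - cuts) <= half_ulp]
    if (length(near) > 0) {
      out[[length(out) + 1L]] <- finding(
        i, "content_exact", near[1], scored$content_exact[i], "info",
        sprintf("exact content %.6f within half a display unit of the %.3f rounding cut",
                scored$content_exact[i], near[1]))
    }
  }
  notes <- attr(records, "qc_notes")
  findings <- dplyr::bind_rows(c(out, if (!is.null(notes)) list(notes)))
  if (nrow(findings) == 0) {
    findings <- tibble::tibble(food_id = character(), name = character(),
                               field_name = character(), listed_value = numeric(),
                               recomputed_value = numeric(), severity = character(),
                               note = character())
  }
  findings
}
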