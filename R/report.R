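#' Configure an end-to-end assessment run
#'
#' Validates and assembles the knobs of [run_assessment()]: input
#' selectors, the authority and EPA+DHA target tiers, the ALA conversion
#' rate, the seafood serving size, and the seed for synthetic inputs.
#'
#' @param composition `"bundled"` for the packaged reference tables, or a
#'   named list/vector of file paths by category (loaded with the
#'   canonical dialect, see [canonical_dialect()]).
#' @param consumption `"synthetic"` for [taiwan_consumption_spec()]
#'   draws, or a path to a consumption table
#'   ([read_consumption_table()]).
#' @param authority Authority for EPA+DHA adequacy, one of `"WHO"`,
#'   `"AHA"`, `"EFSA"`, `"DGA"`.
#' @param ala_authority Authority for ALA adequacy (only `"NIH"` issues
#'   ALA values).
#' @param tiers EPA+DHA scenario targets in g/day (default
#'   `c(0.25, 0.5, 1.0)`).
#' @param conversion_rate Assumed ALA to EPA+DHA conversion (default
#'   0.15).
#' @param oz_grams Grams in the daily 1.1 oz seafood serving (default
#'   31.2; some sources print 34.2).
#' @param epa_dha_only Score aquatic foods on EPA+DHA alone (needs
#'   fatty-acid profiles; default `FALSE`, total omega-3).
#' @param seed Seed for synthetic consumption (default 1).
#' @param n_synthetic Participants per stratum when simulating (default
#'   500).
#' @return A validated `assessment_config` list.
#' @export
assessment_config <- function(composition = "bundled",
                              consumption = "synthetic",
                              authority = "WHO",
                              ala_authority = "NIH",
                              tiers = c(0.25, 0.5, 1.0),
                              conversion_rate = 0.15,
                              oz_grams = 31.2,
                              epa_dha_only = FALSE,
                              seed = 1,
                              n_synthetic = 500) {
  allowed <- c("WHO", "AHA", "EFSA", "DGA", "NIH")
  if (!is.character(authority) || length(authority) != 1 ||
      !authority %in% allowed) {
    abort(sprintf("config error in `authority`: must be one of %s.",
                  paste(allowed, collapse = ", ")))
  }
  if (!identical(ala_authority, "NIH")) {
    abort("config error in `ala_authority`: only NIH issues ALA values here.")
  }
  if (!is.numeric(tiers) || length(tiers) < 1 || any(tiers <= 0)) {
    abort("config error in `tiers`: positive g/day values required.")
  }
  assert_scalar_number(conversion_rate, "conversion_rate", 0, 1)
  assert_scalar_number(oz_grams, "oz_grams", lower = 1)
  assert_scalar_number(seed, "seed")
  if (is.character(composition) && !identical(composition, "bundled") &&
      !all(file.exists(composition))) {
    abort("config error in `composition`: path does not exist.")
  }
  if (is.character(consumption) && !identical(consumption, "synthetic") &&
      !file.exists(consumption)) {
    abort("config error in `consumption`: path does not exist.")
  }
  structure(list(composition = composition, consumption = consumption,
                 authority = authority, ala_authority = ala_authority,
                 tiers = tiers, conversion_rate = conversion_rate,
                 oz_grams = oz_grams, epa_dha_only = epa_dha_only,
                 seed = seed, n_synthetic = n_synthetic),
            class = "assessment_config")
}

load_config_composition <- function(config) {
  if (identical(config$composition, "bundled")) {
    return(bundled_composition())
  }
  paths <- config$composition
  dplyr::bind_rows(lapply(paths, load_composition_table,
                          dialect = canonical_dialect()))
}

load_config_consumption <- function(config) {
  if (identical(config$consumption, "synthetic")) {
    generate_consumption(taiwan_consumption_spec(n = config$n_synthetic),
                         seed = config$seed)$strata
  } else {
    read_consumption_table(config$consumption)
  }
}

#' Run the full omega-3 assessment pipeline
#'
#' Executes every stage of the assessment on one configuration: loads
#' and quality-checks the composition records, scores and ranks foods
#' per category, summarises content bands, derives the daily minimally
#' required consumption against the NIH adult ALA targets (plant foods)
#' and the EPA+DHA tiers (aquatic foods), checks the standard daily
#' seafood serving against the first tier, and estimates stratified ALA
#' and EPA+DHA intake with adequacy flags from consumption statistics.
#' All arithmetic happens in the stage functions; this layer only
#' sequences them and formats output.
#'
#' @param config An [assessment_config()].
#' @param out_dir Optional directory; when given, every table is written
#'   as tab-separated text at full precision alongside a human-readable
#'   `summary.txt` and a `run_log.txt` echoing the configuration.
#' @return (Invisibly) a named list of tibbles: `records`, `qc`,
#'   `scored`, `rankings`, `bands`, `dmrc`, `serving_check`,
#'   `category_contents`, `consumption`, `intake_ala`, `intake_epa_dha`.
#' @examples
#' \donttest{
#' report <- run_assessment(assessment_config(seed = 42))
#' head(report$dmrc)
#' }
#' @export
run_assessment <- function(config = assessment_config(), out_dir = NULL) {
  if (!inherits(config, "assessment_config")) {
    abort("`config` must be created by assessment_config().")
  }
  records <- load_config_composition(config)
  qc <- validate_and_qc(records)
  scored <- score_content(records)
  if (config$epa_dha_only) {
    aquatic <- records$category %in% NUTRIENT_CATEGORIES$EPA_DHA
    scored[aquatic, ] <- score_content(records[aquatic, , drop = FALSE],
                                       epa_dha_only = TRUE)
  }

  rankings <- dplyr::bind_rows(lapply(
    intersect(FOOD_CATEGORIES, unique(scored$category)),
    function(cat) rank_by_content(scored[scored$category == cat, , drop = FALSE])
  ))
  bands <- dplyr::bind_rows(lapply(
    intersect(FOOD_CATEGORIES, unique(scored$category)),
    function(cat) band_distribution(scored, cat)
  ))

  # Daily minimally required consumption: plant foods against the NIH
  # adult ALA targets, aquatic foods against the EPA+DHA tiers.
  registry <- reference_intakes()
  ala_targets <- c(
    male = lookup_reference("ALA", "NIH", "male", 30, registry = registry)$amount_low,
    female = lookup_reference("ALA", "NIH", "female", 30, registry = registry)$amount_low
  )
  plant <- scored[scored$category %in% NUTRIENT_CATEGORIES$ALA, , drop = FALSE]
  aqua <- scored[scored$category %in% NUTRIENT_CATEGORIES$EPA_DHA, , drop = FALSE]
  dmrc <- dplyr::bind_rows(c(
    lapply(names(ala_targets), function(sex) {
      out <- minimal_required_consumption(plant, ala_targets[[sex]])
      out$nutrient <- "ALA"
      out$target_label <- sprintf("NIH %s adult", sex)
      out
    }),
    lapply(config$tiers, function(tier) {
      out <- minimal_required_consumption(aqua, tier)
      out$nutrient <- "EPA_DHA"
      out$target_label <- sprintf("%g mg/day", tier * 1000)
      out
    })
  ))
  dmrc <- dplyr::arrange(dmrc, .data$nutrient, .data$target,
                         .data$grams_exact, .data$name)

  serving_check <- meets_guideline(aqua, config$oz_grams, min(config$tiers))

  contents <- category_mean_content(scored)
  consumption <- load_config_consumption(config)
  intake_ala <- assess_adequacy(
    estimate_intake(consumption, contents, "ALA"),
    authority = config$ala_authority)
  intake_epa_dha <- assess_adequacy(
    estimate_intake(consumption, contents, "EPA_DHA"),
    authority = config$authority)

  report <- list(records = records, qc = qc, scored = scored,
                 rankings = rankings, bands = bands, dmrc = dmrc,
                 serving_check = serving_check,
                 category_contents = contents, consumption = consumption,
                 intake_ala = intake_ala, intake_epa_dha = intake_epa_dha)
  class(report) <- "omega3_report"

  if (!is.null(out_dir)) {
    write_report(report, config, out_dir)
  }
  invisible(report)
}

write_tsv <- function(x, path) {
  df <- as.data.frame(x)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      df[[col]] <- format(df[[col]], digits = 15, trim = TRUE,
                          scientific = FALSE)
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
}

write_report <- function(report, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("qc", "scored", "rankings", "bands", "dmrc", "serving_check",
              "category_contents", "consumption", "intake_ala",
              "intake_epa_dha")
  for (tab in tables) {
    write_tsv(report[[tab]], file.path(out_dir, paste0(tab, ".tsv")))
  }
  write_composition_table(report$records, file.path(out_dir, "records.tsv"))

  # Human-readable summary at the conventional display precisions
  # (2 dp for g/g contents, 3 dp for g/day amounts).
  txt <- c(
    "Omega-3 assessment summary",
    "==========================",
    "",
    "Top foods by omega-3 content (g/g):",
    utils::capture.output(print(as.data.frame(
      dplyr::mutate(head(dplyr::arrange(report$scored,
                                        dplyr::desc(.data$content_exact)), 10),
                    content_exact = sprintf("%.4f", .data$content_exact),
                    content_display = sprintf("%.2f", .data$content_display))),
      row.names = FALSE)),
    "",
    "Content bands by category:",
    utils::capture.output(print(as.data.frame(
      dplyr::mutate(report$bands, fraction = sprintf("%.3f", .data$fraction))),
      row.names = FALSE)),
    "",
    "Most efficient foods per target (g/day, half-up to whole grams):",
    utils::capture.output(print(as.data.frame(
      dplyr::slice_head(dplyr::group_by(report$dmrc, .data$target_label), n = 3)[
        c("target_label", "name", "grams_exact", "grams_rounded")] |>
        dplyr::mutate(grams_exact = sprintf("%.3f", .data$grams_exact))),
      row.names = FALSE))
  )
  writeLines(txt, file.path(out_dir, "summary.txt"))

  log <- c(
    sprintf("run time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    "configuration:",
    sprintf("  composition: %s", paste(config$composition, collapse = ", ")),
    sprintf("  consumption: %s", paste(config$consumption, collapse = ", ")),
    sprintf("  authority (EPA+DHA): %s", config$authority),
    sprintf("  authority (ALA): %s", config$ala_authority),
    sprintf("  tiers (g/day): %s", paste(config$tiers, collapse = ", ")),
    sprintf("  conversion_rate: %s", config$conversion_rate),
    sprintf("  oz_grams: %s", config$oz_grams),
    sprintf("  epa_dha_only: %s", config$epa_dha_only),
    sprintf("  seed: %s", config$seed),
    sprintf("  n_synthetic: %s", config$n_synthetic),
    sprintf("records loaded: %d; QC findings: %d (%d mismatch)",
            nrow(report$records), nrow(report$qc),
            sum(report$qc$severity == "mismatch"))
  )
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.omega3_report <- function(x, ...) {
  cat("<omega3_report>\n")
  cat(sprintf("  %d composition records, %d QC findings (%d mismatch)\n",
              nrow(x$records), nrow(x$qc), sum(x$qc$severity == "mismatch")))
  top <- x$rankings[x$rankings$rank == 1, , drop = FALSE]
  cat("  top food per category:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-10s %s (%.2f g/g)\n", top$category[i], top$name[i],
                top$content_display[i]))
  }
  cat(sprintf("  intake strata: %d (ALA), %d (EPA+DHA)\n",
              nrow(x$intake_ala), nrow(x$intake_epa_dha)))
  invisible(x)
}
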