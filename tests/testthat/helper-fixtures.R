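# Independent re-parse of a bundled table: raw printed numbers, base R
# arithmetic only. Used as the oracle against the package's loader and
# scorer.
raw_bundled <- function(file) {
  path <- system.file("extdata", file, package = "omega3intake",
                      mustWork = TRUE)
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  num <- function(x) suppressWarnings(as.numeric(sub("^<\\s*", "", trimws(x))))
  raw$share <- num(raw$omega3_pct_fat) / 100
  raw$fat <- num(raw$fat_pct) / 100
  raw$listed <- num(raw$omega3_g_per_g)
  raw$listed_censored <- grepl("^<", trimws(raw$omega3_g_per_g))
  raw
}

# Half-up rounding oracle, written without reference to the package.
oracle_round2 <- function(x) floor(x * 100 + 0.5 + 1e-9) / 100

# A minimal composition record with a consistent fatty-acid profile.
make_profile_record <- function(name = "test food", category = "fish",
                                fat = 0.1, ala = 1, epa = 1, dha = 1,
                                sfa = 10, mufa = 10, pufa = 10,
                                share = NA_real_) {
  tibble::tibble(
    food_id = gsub(" ", "_", name), name = name,
    species_binomial = NA_character_, category = category,
    preparation = "raw", fat_fraction = fat,
    omega3_share_of_fat = share, share_censored = FALSE,
    ala = ala, epa = epa, dha = dha,
    sfa_total = sfa, mufa_total = mufa, pufa_total = pufa,
    listed_content = NA_real_, listed_censored = FALSE
  )
}

write_tmp_table <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
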