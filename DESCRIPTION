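Package: omega3intake
Title: Omega-3 Content Scoring and Dietary Intake Adequacy Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for database-driven assessment of dietary omega-3 fatty
    acid supply. Computes the omega-3 content (grams of ALA+EPA+DHA per
    gram of food) of edible oils, nuts and seeds, fish, crustaceans and
    mollusks from fatty-acid composition tables, ranks foods and
    classifies them into content bands, derives the daily minimally
    required consumption to meet authority-specific recommendations
    (NIH ALA targets; WHO/AHA/EFSA/DGA EPA+DHA tiers, with an optional
    ALA-to-EPA+DHA conversion), and estimates age- and sex-stratified
    population intake by multiplying category-mean contents with food
    consumption statistics, flagging adequacy per stratum. Bundles
    reference composition tables for Taiwanese foods and a synthetic
    consumption-survey generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
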