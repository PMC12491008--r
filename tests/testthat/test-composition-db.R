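test_that("bundled tables load with the printed dimensions and values", {
  oils <- bundled_composition("edible_oil")
  expect_equal(nrow(oils), 23)
  expect_equal(oils$name[1], "Flaxseed oil")
  expect_equal(oils$fat_fraction[1], 0.928)
  expect_equal(oils$omega3_share_of_fat[1], 0.577)

  counts <- vapply(c(nut_seed = "nut_seed", fish = "fish",
                     crustacean = "crustacean", mollusk = "mollusk"),
                   function(cat) nrow(bundled_composition(cat)), integer(1))
  expect_equal(unname(counts), c(19L, 48L, 21L, 15L))

  all_records <- bundled_composition()
  expect_equal(nrow(all_records), 23 + 19 + 48 + 21 + 15)
  expect_false(anyDuplicated(all_records$food_id) > 0)
})

test_that("percent columns become fractions and censored cells keep their bound", {
  nuts <- bundled_composition("nut_seed")
  almond <- nuts[nuts$name == "Almond", ]
  expect_equal(almond$omega3_share_of_fat, 0.0005) # printed "< 0.05" %
  expect_true(almond$share_censored)

  oils <- bundled_composition("edible_oil")
  grapeseed <- oils[oils$name == "Grapeseed oil", ]
  expect_equal(grapeseed$listed_content, 0.01) # printed "< 0.01" g/g
  expect_true(grapeseed$listed_censored)
  # values in [0,1] throughout after percent conversion
  expect_true(all(oils$fat_fraction >= 0 & oils$fat_fraction <= 1))
  expect_true(all(oils$omega3_share_of_fat >= 0 & oils$omega3_share_of_fat <= 1))
})

test_that("an empty file with a valid header loads as an empty collection", {
  path <- write_tmp_table("name\tomega3_pct_fat\tfat_pct\tomega3_g_per_g")
  records <- load_composition_table(
    path, composition_dialect(share = "omega3_pct_fat",
                              listed_content = "omega3_g_per_g",
                              category_value = "fish",
                              percent = c("omega3_pct_fat", "fat_pct")))
  expect_equal(nrow(records), 0)
})

test_that("a missing mandatory column fails the load naming the column", {
  path <- write_tmp_table(c("name\tomega3_pct_fat", "eel\t10"))
  expect_error(
    load_composition_table(
      path, composition_dialect(share = "omega3_pct_fat",
                                category_value = "fish")),
    "fat_pct")
})

test_that("bad rows are rejected with diagnostics and ordering is preserved", {
  path <- write_tmp_table(c(
    "name\tomega3_pct_fat\tfat_pct\tcategory",
    "good one\t10\t20\tfish",
    "no share\t\t20\tfish",
    "bad number\tabc\t20\tfish",
    "bad category\t10\t20\tcereal",
    "good two\t5\t30\tmollusk",
    "fat too high\t10\t150\tfish"
  ))
  dialect <- composition_dialect(share = "omega3_pct_fat", category = "category",
                                 percent = c("omega3_pct_fat", "fat_pct"))
  expect_warning(records <- load_composition_table(path, dialect),
                 "rejected")
  expect_equal(records$name, c("good one", "good two"))
  rejected <- attr(records, "rejected")
  expect_equal(rejected$row, c(2L, 3L, 4L, 6L))
  expect_match(rejected$reason[rejected$name == "bad category"], "category")
  expect_match(rejected$reason[rejected$name == "fat too high"], "\\[0, 1\\]")
})

test_that("profile invariants are enforced on load", {
  header <- "name\tfat\tala\tepa\tdha\tsfa\tmufa\tpufa"
  dialect <- composition_dialect(
    fat = "fat", ala = "ala", epa = "epa", dha = "dha",
    sfa = "sfa", mufa = "mufa", pufa = "pufa", category_value = "fish")
  # omega-3 masses exceeding total PUFA reject the row
  path <- write_tmp_table(c(header, "impossible\t0.1\t5\t2\t2\t10\t10\t6"))
  expect_warning(records <- load_composition_table(path, dialect),
                 "pufa_total")
  expect_equal(nrow(records), 0)
  # a consistent profile loads and needs no share column
  path2 <- write_tmp_table(c(header, "plausible\t0.1\t1\t1\t1\t10\t10\t6"))
  records2 <- load_composition_table(path2, dialect)
  expect_equal(nrow(records2), 1)
  expect_true(is.na(records2$omega3_share_of_fat))
})

test_that("the raw record wins when duplicates share a food identifier", {
  path <- write_tmp_table(c(
    "id\tname\tomega3_pct_fat\tfat_pct",
    "eel\tEel (cooked)\t12\t20",
    "eel\tEel (raw)\t11\t19",
    "carp\tCarp\t5\t8"
  ))
  dialect <- composition_dialect(
    food_id = "id", share = "omega3_pct_fat", category_value = "fish",
    preparation_value = "raw", percent = c("omega3_pct_fat", "fat_pct"))
  # both eel rows default to raw -> first kept; now mark one cooked
  path2 <- write_tmp_table(c(
    "id\tname\tprep\tomega3_pct_fat\tfat_pct",
    "eel\tEel (cooked)\tcooked\t12\t20",
    "eel\tEel (raw)\traw\t11\t19",
    "carp\tCarp\traw\t5\t8"
  ))
  dialect2 <- composition_dialect(
    food_id = "id", preparation = "prep", share = "omega3_pct_fat",
    category_value = "fish", percent = c("omega3_pct_fat", "fat_pct"))
  records <- load_composition_table(path2, dialect2)
  expect_equal(nrow(records), 2)
  expect_equal(records$name[records$food_id == "eel"], "Eel (raw)")
})

test_that("writing and re-loading a collection is field-identical", {
  for (cat in c("edible_oil", "mollusk")) {
    records <- bundled_composition(cat)
    attr(records, "qc_notes") <- NULL
    path <- withr::local_tempfile(fileext = ".tsv")
    write_composition_table(records, path)
    reloaded <- load_composition_table(path, canonical_dialect())
    attr(reloaded, "rejected") <- NULL
    expect_equal(as.data.frame(reloaded), as.data.frame(records))
  }
})

test_that("QC recomputation confirms every listed value outside the known fish anomalies", {
  for (cat in c("edible_oil", "nut_seed", "crustacean", "mollusk")) {
    qc <- validate_and_qc(bundled_composition(cat))
    expect_equal(sum(qc$severity == "mismatch"), 0, info = cat)
  }
  qc_fish <- validate_and_qc(bundled_composition("fish"))
  mismatches <- qc_fish[qc_fish$severity == "mismatch", ]
  expect_setequal(mismatches$name, c("Silverfish", "Yellow croaker", "Runner"))
  silver <- mismatches[mismatches$name == "Silverfish", ]
  expect_equal(silver$listed_value, 0.02)
  expect_lt(silver$recomputed_value, 0.02) # 18.3% of 2.0% fat is 0.00366 g/g
})

test_that("QC is deterministic and surfaces the oil row-count note", {
  records <- bundled_composition()
  expect_identical(validate_and_qc(records), validate_and_qc(records))
  qc <- validate_and_qc(records)
  count_note <- qc[qc$field_name == "row_count", ]
  expect_equal(nrow(count_note), 1)
  expect_equal(count_note$severity, "info")
  expect_equal(c(count_note$listed_value, count_note$recomputed_value),
               c(22, 23))
})

test_that("explicit listed contents override the stored column", {
  records <- bundled_composition("crustacean")
  wrong <- rep(0.5, nrow(records))
  qc <- validate_and_qc(records, listed_contents = wrong)
  expect_equal(sum(qc$severity == "mismatch"), nrow(records))
})
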