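one_stratum <- function(category, mean, p50 = mean, p95 = mean,
                        sex = "female", age_low = 19, age_high = 65) {
  tibble::tibble(sex = sex, age_low = age_low, age_high = age_high,
                 body_weight = 57, category = category,
                 mean = mean, p50 = p50, p95 = p95)
}

test_that("category mean content is the arithmetic mean of exact contents", {
  two <- score_content(dplyr::bind_rows(
    make_profile_record("a", share = 0.5, fat = 0.2),  # 0.10
    make_profile_record("b", share = 0.6, fat = 0.5))) # 0.30
  expect_equal(category_mean_content(two)$mean_content, 0.2)

  single <- score_content(make_profile_record(share = 0.3, fat = 0.4))
  expect_equal(category_mean_content(single)$mean_content, 0.12)

  # oracle: mean of the 15 printed mollusk share x fat products
  raw <- raw_bundled("mollusks.tsv")
  oracle_mean <- mean(raw$share * raw$fat)
  got <- category_mean_content(score_content(bundled_composition("mollusk")))
  expect_equal(got$mean_content, oracle_mean)
  expect_equal(got$n, 15L)

  expect_error(category_mean_content(two, categories = "mollusk"), "mollusk")
})

test_that("intake contributions are consumption times content, summed exactly", {
  contents <- c(fish = 0.08, crustacean = 0.005, mollusk = 0.003)
  cons <- dplyr::bind_rows(one_stratum("fish", 10),
                           one_stratum("crustacean", 4),
                           one_stratum("mollusk", 2))
  est <- estimate_intake(cons, contents, "EPA_DHA")
  expect_equal(est$mean[est$category == "fish"], 0.8)
  total <- est[est$category == "all_foods", ]
  expect_identical(total$mean, 0.8 + 0.02 + 0.006)

  zero <- estimate_intake(dplyr::bind_rows(one_stratum("fish", 0),
                                           one_stratum("mollusk", 0)),
                          contents, "EPA_DHA")
  expect_true(all(c(zero$mean, zero$p50, zero$p95) == 0))

  expect_error(estimate_intake(one_stratum("mollusk", 2),
                               c(fish = 0.08), "EPA_DHA"), "mollusk")
  expect_error(estimate_intake(one_stratum("fish", 2), contents, "ALA"),
               "no rows")
})

test_that("totals are exact category sums for every statistic", {
  withr::with_seed(31, {
    for (i in 1:10) {
      cons <- dplyr::bind_rows(lapply(c("edible_oil", "nut_seed"), function(cat) {
        p50 <- runif(1, 0, 5); p95 <- p50 + runif(1, 0, 20)
        one_stratum(cat, mean = runif(1, 0, 10), p50 = p50, p95 = p95)
      }))
      contents <- c(edible_oil = runif(1, 0, 0.5), nut_seed = runif(1, 0, 0.3))
      est <- estimate_intake(cons, contents, "ALA")
      contrib <- est[est$category != "all_foods", ]
      total <- est[est$category == "all_foods", ]
      for (stat in c("mean", "p50", "p95")) {
        expect_identical(total[[stat]], sum(contrib[[stat]]))
      }
    }
  })
})

test_that("doubling consumption doubles every contribution and total", {
  cons <- dplyr::bind_rows(one_stratum("fish", 7, 2, 30),
                           one_stratum("crustacean", 3, 1, 9),
                           one_stratum("mollusk", 1, 0.2, 4))
  contents <- c(fish = 0.0127, crustacean = 0.0027, mollusk = 0.0036)
  est1 <- estimate_intake(cons, contents, "EPA_DHA")
  cons2 <- dplyr::mutate(cons, mean = 2 * mean, p50 = 2 * p50, p95 = 2 * p95)
  est2 <- estimate_intake(cons2, contents, "EPA_DHA")
  expect_equal(est2$mean, 2 * est1$mean)
  expect_equal(est2$p50, 2 * est1$p50)
  expect_equal(est2$p95, 2 * est1$p95)
})

test_that("published category columns sum to the all-foods column on the fixtures", {
  ala <- bundled_intake("ALA")
  for (sex in c("male", "female")) {
    tab <- ala[ala$sex == sex, ]
    wide <- tidyr::pivot_wider(tab[c("age_low", "category", "mean")],
                               names_from = "category", values_from = "mean")
    residual <- wide$edible_oil + wide$nut_seed - wide$all_foods
    if (sex == "female") {
      expect_equal(max(abs(residual)), 0) # exact for every female row
    } else {
      expect_lte(max(abs(residual)), 0.001 + 1e-9) # one 0.001 print residual
    }
    # percentile columns: printed values carry up to 0.001 rounding residue
    for (stat in c("p50", "p95")) {
      wide_s <- tidyr::pivot_wider(tab[c("age_low", "category", stat)],
                                   names_from = "category",
                                   values_from = dplyr::all_of(stat))
      expect_lte(max(abs(wide_s$edible_oil + wide_s$nut_seed - wide_s$all_foods)),
                 0.001 + 1e-9)
    }
  }

  epa <- bundled_intake("EPA_DHA")
  adults <- epa[epa$age_low == 19, ]
  for (sex in c("male", "female")) {
    tab <- adults[adults$sex == sex, ]
    expect_equal(sum(tab$mean[tab$category != "all_foods"]),
                 tab$mean[tab$category == "all_foods"])
  }
})

test_that("adequacy flags reproduce the published intake markers", {
  # EPA+DHA: every marked cell is exactly a statistic >= 250 mg/day
  epa <- bundled_intake("EPA_DHA")
  est <- tibble::tibble(sex = epa$sex, age_low = epa$age_low,
                        age_high = epa$age_high, nutrient = "EPA_DHA",
                        category = epa$category, mean = epa$mean,
                        p50 = epa$p50, p95 = epa$p95)
  flagged <- assess_adequacy(est, authority = "WHO")
  expect_equal(flagged$mean_adequate, epa$mean_flag == 1)
  expect_equal(flagged$p50_adequate, epa$p50_flag == 1)
  expect_equal(flagged$p95_adequate, epa$p95_flag == 1)

  # ALA: the all-foods totals are marked adequate at mean and P95 but not
  # at the median, for every stratum of both sexes
  ala <- bundled_intake("ALA")
  totals <- ala[ala$category == "all_foods", ]
  est_ala <- tibble::tibble(sex = totals$sex, age_low = totals$age_low,
                            age_high = totals$age_high, nutrient = "ALA",
                            category = totals$category, mean = totals$mean,
                            p50 = totals$p50, p95 = totals$p95)
  flagged_ala <- assess_adequacy(est_ala, authority = "NIH")
  expect_equal(flagged_ala$mean_adequate, totals$mean_flag == 1)
  expect_equal(flagged_ala$p50_adequate, totals$p50_flag == 1)
  expect_equal(flagged_ala$p95_adequate, totals$p95_flag == 1)
})

test_that("adequacy uses the lower bound, >= at the boundary, per stratum", {
  est <- tibble::tibble(sex = "female", age_low = 19, age_high = 65,
                        nutrient = "EPA_DHA", category = "all_foods",
                        mean = 0.25, p50 = 0.2499999, p95 = 0.5)
  flagged <- assess_adequacy(est, authority = "WHO")
  expect_true(flagged$mean_adequate)   # equality counts as adequate
  expect_false(flagged$p50_adequate)
  expect_equal(flagged$reference, 0.25)

  # stratum spanning several NIH groups maps to the oldest contained group
  est2 <- tibble::tibble(sex = "male", age_low = 0, age_high = 3,
                         nutrient = "ALA", category = "all_foods",
                         mean = 0.8, p50 = 0.1, p95 = 2)
  flagged2 <- assess_adequacy(est2, authority = "NIH")
  expect_equal(flagged2$reference, 0.7) # the 1-3 y value, not the infant one
  expect_true(flagged2$mean_adequate)

  expect_error(assess_adequacy(est, authority = "NIH"), "no EPA_DHA")
})

test_that("raising a contribution never flips adequacy off", {
  withr::with_seed(41, {
    for (i in 1:10) {
      base <- one_stratum("fish", runif(1, 0, 0.5), runif(1, 0, 0.2),
                          runif(1, 0, 1))
      bigger <- dplyr::mutate(base, mean = mean + runif(1, 0, 1),
                              p50 = p50 + runif(1, 0, 1),
                              p95 = p95 + runif(1, 0, 1))
      f1 <- assess_adequacy(estimate_intake(base, c(fish = 1), "EPA_DHA"))
      f2 <- assess_adequacy(estimate_intake(bigger, c(fish = 1), "EPA_DHA"))
      expect_true(all(f2$mean_adequate >= f1$mean_adequate))
      expect_true(all(f2$p50_adequate >= f1$p50_adequate))
      expect_true(all(f2$p95_adequate >= f1$p95_adequate))
    }
  })
})

test_that("consumption tables validate their schema and statistics", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sex\tage_low\tage_high\tbody_weight\tcategory\tmean\tp50\tp95",
               "male\t19\t65\t68\tfish\t20\t8\t60"), path)
  cons <- read_consumption_table(path)
  expect_equal(cons$p95, 60)

  writeLines(c("sex\tage_low\tage_high\tbody_weight\tcategory\tmean\tp50\tp95",
               "male\t19\t65\t68\tfish\t20\t8\t5"), path)
  expect_error(read_consumption_table(path), "p95")

  writeLines("sex\tage_low\tcategory\tmean", path)
  expect_error(read_consumption_table(path), "missing column")
})
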