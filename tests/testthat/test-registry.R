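test_that("packaged registry loads 74 validated countries with printed values", {
  countries <- load_country_table()
  expect_equal(nrow(countries), 74)

  kenya <- countries[countries$country_id == "kenya", ]
  expect_equal(kenya$adol_pop_2010, 9213000)
  expect_equal(kenya$hiv_prev_boys, 0.0117)
  expect_equal(kenya$hiv_prev_girls, 0.0179)
  expect_equal(kenya$sex_active_15_19_boys, 0.612)
  expect_equal(kenya$sex_active_15_19_girls, 0.481)

  angola <- countries[countries$country_id == "angola", ]
  expect_equal(angola$sex_active_10_14_boys, 0.0894)
  expect_equal(angola$sex_active_10_14_boys_flag, "regional_avg")

  expect_true(all(countries$who_region %in%
    c("AFR_D", "AFR_E", "AMR_B", "AMR_D", "EMR_D", "EUR_B", "SEAR_B",
      "SEAR_D", "WPR_B")))

  expect_setequal(
    countries$country_id[countries$excluded_from_maternity],
    c("botswana", "democratic_peoples_republic_of_korea",
      "sao_tome_and_principe", "solomon_islands", "turkmenistan",
      "uzbekistan"))
  expect_equal(countries$country_id[countries$excluded_from_programme],
               "somalia")
  expect_equal(sum(countries$income_group == "low"), 35)
  expect_equal(sum(countries$income_group == "middle"), 39)
})

test_that("country loader rejects malformed input with classed errors", {
  src <- readLines(system.file("extdata", "countries.csv",
                               package = "afhscost"))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(src[1], empty)
  expect_error(load_country_table(empty), class = "afhscost_integrity_error")

  short <- withr::local_tempfile(fileext = ".csv")
  writeLines(src[-2], short)
  expect_error(load_country_table(short), class = "afhscost_integrity_error")

  noreg <- withr::local_tempfile(fileext = ".csv")
  writeLines(gsub("who_region", "region", src), noreg)
  expect_error(load_country_table(noreg), class = "afhscost_schema_error")

  badfrac <- withr::local_tempfile(fileext = ".csv")
  writeLines(gsub("0.24,0.48", "120,0.48", src, fixed = TRUE), badfrac)
  expect_error(load_country_table(badfrac),
               regexp = "hiv_prev_boys.*angola",
               class = "afhscost_validation_error")
})

test_that("impute_field applies population-weighted regional then global means", {
  toy <- dplyr::bind_rows(
    make_country("a1", adol_pop = 1000, who_region = "AFR_E", hiv_boys = 0.10),
    make_country("a2", adol_pop = 3000, who_region = "AFR_E", hiv_boys = 0.20),
    make_country("a3", adol_pop = 9999, who_region = "AFR_E", hiv_boys = NA),
    make_country("e1", adol_pop = 5000, who_region = "EMR_D", hiv_boys = NA))

  out <- impute_field(toy, "hiv_prev_boys")
  # regional weighted mean: (1000*0.10 + 3000*0.20) / 4000
  expect_equal(out$hiv_prev_boys[3], 0.175)
  expect_equal(out$hiv_prev_boys_flag[3], "regional_avg")
  # EMR_D has no observed values: global weighted mean over a1, a2
  expect_equal(out$hiv_prev_boys[4], 0.175)
  expect_equal(out$hiv_prev_boys_flag[4], "global_avg")

  # imputed values lie within the observed range
  expect_true(all(out$hiv_prev_boys >= 0.10 & out$hiv_prev_boys <= 0.20))
  # idempotent; and a no-op on complete data
  expect_identical(impute_field(out, "hiv_prev_boys"), out)

  expect_error(impute_field(toy, "nonesuch"),
               class = "afhscost_validation_error")
  allna <- toy
  allna$hiv_prev_girls <- NA_real_
  expect_error(impute_field(allna, "hiv_prev_girls"),
               class = "afhscost_validation_error")
})

test_that("intervention catalogue matches the printed shares and targets", {
  specs <- load_intervention_table()
  expect_equal(nrow(specs), 19)
  expect_equal(length(unique(specs$intervention_group)), 8)

  anc <- specs[specs$intervention_id == "anc", ]
  expect_equal(c(anc$share_hospital, anc$share_primary, anc$share_community),
               c(0.90, 0.05, 0.05))

  ost <- specs[specs$intervention_id == "ost", ]
  expect_equal(ost$target_coverage, 0.50)
  expect_equal(ost$share_primary, 1)
  expect_equal(c(ost$coverage_lo, ost$coverage_hi), c(0, 0.67))

  expect_true(all(specs$target_coverage[specs$intervention_id != "ost"] == 0.95))
  expect_true(all(abs(specs$share_hospital + specs$share_primary +
                        specs$share_community - 1) <= 1e-9))

  htc <- specs[specs$intervention_id == "htc", ]
  expect_equal(c(htc$coverage_lo, htc$coverage_hi), c(0, 0.35))

  childbirth <- specs[specs$intervention_id == "childbirth_care", ]
  expect_equal(childbirth$coverage_lo, 0.988)
  expect_equal(c(childbirth$share_hospital, childbirth$share_primary),
               c(0.25, 0.75))
})

test_that("intervention loader rejects invalid share and id sets", {
  src <- readLines(system.file("extdata", "interventions.csv",
                               package = "afhscost"))
  badshare <- withr::local_tempfile(fileext = ".csv")
  writeLines(gsub("95,90,5,5,female", "95,80,30,0,female", src), badshare)
  expect_error(load_intervention_table(badshare),
               class = "afhscost_validation_error")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(src, src[2]), dup)
  expect_error(load_intervention_table(dup),
               class = "afhscost_validation_error")
})

test_that("the 20 service characteristics partition the quality dimensions", {
  chars <- load_characteristics_table()
  expect_equal(nrow(chars), 20)
  expect_equal(sort(chars$number), 1:20)
  counts <- table(chars$dimension)
  expect_equal(counts[["equitable"]], 3)
  expect_equal(counts[["accessible"]], 5)
  expect_equal(counts[["acceptable"]], 7)
  expect_equal(counts[["appropriate"]], 1)
  expect_equal(counts[["effective"]], 4)
})
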