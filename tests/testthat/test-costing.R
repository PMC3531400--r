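toy_ingredients <- function() {
  tibble::tibble(
    intervention_id = c("testint", "testint"),
    item = c("drug", "visit"),
    category = c("drug", "service_delivery"),
    quantity_per_case = c(2, 1),
    unit_price_usd = c(0.5, NA),
    delivery_point = "any")
}

test_that("cost per case is quantity times price, weighted across levels", {
  spec <- make_spec()
  uc <- tibble::tibble(country_id = "testland",
                       level = c("hospital", "primary", "community"),
                       unit_cost = c(10, 3, 1))
  cpc <- cost_per_case(spec, toy_ingredients(), uc, "testland")
  expect_equal(cpc[["commodities"]], 1.00)
  expect_equal(cpc[["service_delivery"]], 3.00)
  expect_equal(sum(cpc), 4.00)

  # childbirth-style 25% hospital / 75% primary with visit costs 10 and 2
  mixed <- make_spec(shares = c(hospital = 0.25, primary = 0.75, community = 0))
  uc2 <- tibble::tibble(country_id = "testland",
                        level = c("hospital", "primary"),
                        unit_cost = c(10, 2))
  cpc2 <- cost_per_case(mixed, toy_ingredients(), uc2, "testland")
  expect_equal(cpc2[["service_delivery"]], 4.00)

  # all quantities zero: zero cost per case
  nil <- toy_ingredients()
  nil$quantity_per_case <- 0
  expect_equal(unname(cost_per_case(spec, nil, uc, "testland")), c(0, 0))

  # missing unit cost for an active delivery point names the country/level
  expect_error(cost_per_case(spec, toy_ingredients(),
                             uc[uc$level != "primary", ], "testland"),
               regexp = "testland.*primary",
               class = "afhscost_validation_error")
})

test_that("intervention cost is cases times cost per case, with exclusions", {
  country <- make_country(growth = 0)
  spec <- make_spec()
  need <- tibble::tibble(country_id = "testland", intervention_id = "testint",
                         year = 2011:2015, persons_in_need = 1000,
                         basis_used = "all_adolescents")
  traj <- coverage_trajectory("testland", "testint", baseline = 0.45,
                              target = 0.95)
  cpc <- c(commodities = 1, service_delivery = 3)
  cube <- intervention_cost(country, spec, 2011:2015, need, traj, cpc)
  # 2011 increment is (1/5)(0.95 - 0.45) = 0.10, so 100 cases at $4
  y1 <- cube[cube$year == 2011, ]
  expect_equal(sum(y1$amount), 400)
  expect_equal(y1$amount[y1$cost_category == "commodities"], 100)

  # baseline at or above target: clamped to zero cost
  flat <- coverage_trajectory("testland", "testint", baseline = 0.95,
                              target = 0.95)
  expect_equal(intervention_cost(country, spec, 2011:2015, need, flat,
                                 cpc)$amount,
               rep(0, 10))

  # maternity-model intervention in an excluded country emits no records
  excl <- make_country(excluded_maternity = TRUE)
  mat <- make_spec(costed_in = "maternity_model")
  need_mat <- need
  cube_mat <- intervention_cost(excl, mat, 2011:2015, need_mat, traj, cpc)
  expect_equal(nrow(cube_mat), 0)

  # mismatched keys abort
  bad_need <- need
  bad_need$country_id <- "elsewhere"
  expect_error(intervention_cost(country, spec, 2011:2015, bad_need, traj, cpc),
               class = "afhscost_validation_error")
})

test_that("programme costs follow their scaling drivers", {
  country <- make_country(adol_pop = 1e6, growth = 0)
  drivers <- tibble::tibble(country_id = "testland", n_districts = 10,
                            n_facilities = 100)
  mgmt <- tibble::tibble(activity_id = "pm", category = "management",
                         level = "national", item = c("meetings", "policy"),
                         quantity = c(10, 1), unit_price_usd = c(2000, 30000),
                         scaling_driver = "per_country_year")
  cube <- programme_cost(country, mgmt, 2011:2015, drivers)
  expect_equal(cube$amount, rep(50000, 5))
  expect_equal(unique(cube$cost_category), "programme")
  expect_equal(unique(cube$programme_category), "management")

  iec <- tibble::tibble(activity_id = "iec", category = "IEC",
                        level = "national", item = "materials",
                        quantity = 100, unit_price_usd = 1,
                        scaling_driver = "per_population")
  small <- programme_cost(country, iec, 2011:2015, drivers)
  big <- programme_cost(make_country(adol_pop = 2e6, growth = 0), iec,
                        2011:2015, drivers)
  expect_equal(big$amount, 2 * small$amount)
  # doubling population leaves driver-based activities unchanged
  big_mgmt <- programme_cost(make_country(adol_pop = 2e6, growth = 0), mgmt,
                             2011:2015, drivers)
  expect_equal(big_mgmt$amount, cube$amount)

  # programme-excluded country (Somalia in the registry) emits no records
  som <- make_country(excluded_programme = TRUE)
  expect_equal(nrow(programme_cost(som, mgmt, 2011:2015, drivers)), 0)

  # missing driver count aborts
  fac <- mgmt
  fac$scaling_driver <- "per_facility"
  expect_error(programme_cost(country, fac, 2011:2015,
                              tibble::tibble(country_id = "testland",
                                             n_districts = 10,
                                             n_facilities = NA)),
               class = "afhscost_validation_error")

  # per_population is reserved for IEC
  bad <- mgmt
  bad$scaling_driver <- "per_population"
  expect_error(programme_cost(country, bad, 2011:2015, drivers),
               class = "afhscost_validation_error")
})

test_that("scaling all prices by k scales every cube cell by k", {
  toy <- make_toy_worked_example()
  base <- run_scenario(toy$config)$cube
  scaled <- run_scenario(scale_prices(toy$config, 3))$cube
  m <- join_cubes(base, scaled)
  expect_equal(m$amount_b, 3 * m$amount_a, tolerance = 1e-12)
})

test_that("raising a baseline below target weakly decreases incremental cost", {
  toy <- make_toy_worked_example()
  base_total <- sum(run_scenario(toy$config)$cube$amount)
  cfg <- toy$config
  i <- cfg$baselines$country_id == "alpha" &
       cfg$baselines$intervention_id == "toy_universal"
  cfg$baselines$baseline[i] <- 0.6  # up from 0.2
  higher <- do.call(afhs_config, unclass(cfg))
  expect_lt(sum(run_scenario(higher)$cube$amount), base_total)
})

test_that("with zero growth, intervention cost in year 2010+k scales with k", {
  toy <- make_toy_worked_example()
  cube <- run_scenario(toy$config)$cube
  iv <- cube[cube$cost_category != "programme", ]
  per_k <- tapply(iv$amount / (iv$year - 2010),
                  paste(iv$country_id, iv$intervention_id, iv$cost_category),
                  function(v) diff(range(v)))
  expect_true(all(per_k < 1e-9))
})
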