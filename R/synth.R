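#' Synthetic-configuration settings
#'
#' The detailed unit prices and ingredient quantities behind the model live
#' in external price databases; the generator stands in for them with
#' seeded, internally consistent synthetic tables so the whole pipeline is
#' testable offline. Structural inputs (the country registry, the
#' intervention catalogue and its printed delivery-point shares and ranges)
#' are never randomized -- only prices, baselines, need shares, growth rates
#' and driver counts are drawn.
#'
#' @param seed Integer seed fixing all generated outputs.
#' @param n_countries Number of countries (74 at most; smaller registries
#'   are sampled for fast tests).
#' @param price_dispersion Coefficient of variation of the log-normal price
#'   noise around the level/item anchors.
#' @param baseline_mode `"range_uniform"` draws baselines (and need shares)
#'   uniformly within each intervention's admissible range;
#'   `"range_midpoint"` pins them at the range midpoint.
#' @param growth_rate_range Range the per-country annual population growth
#'   rate is drawn from.
#' @return An `afhs_synth_config` list.
#' @export
synth_config <- function(seed, n_countries = 74, price_dispersion = 0.3,
                         baseline_mode = c("range_uniform", "range_midpoint"),
                         growth_rate_range = c(0.005, 0.03)) {
  baseline_mode <- match.arg(baseline_mode)
  if (n_countries > 74) {
    abort_validation("the registry is fixed at 74 countries; n_countries > 74")
  }
  if (n_countries < 1) {
    abort_validation("n_countries must be at least 1")
  }
  if (price_dispersion < 0) {
    abort_validation("price_dispersion must be non-negative")
  }
  structure(list(seed = as.integer(seed), n_countries = as.integer(n_countries),
                 price_dispersion = price_dispersion,
                 baseline_mode = baseline_mode,
                 growth_rate_range = growth_rate_range),
            class = "afhs_synth_config")
}

# Illustrative service-delivery anchors (US$ 2008 per contact):
# hospital visit/bed-day > primary-facility visit > community contact.
SERVICE_COST_ANCHORS <- c(hospital = 12, primary = 3, community = 1.2)

lognorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog) # mean 1
}

#' Generate a complete synthetic model configuration
#'
#' Builds every table the scenario runner loads, reproducibly from the
#' seed: per-country baselines and need shares within each intervention's
#' admissible range, per-country service unit costs log-normally dispersed
#' around level-specific anchors, commodity prices dispersed around the
#' packaged illustrative ingredient prices, growth rates, and
#' district/facility counts derived from population size.
#'
#' @param sc An `afhs_synth_config` from [synth_config()].
#' @param options Model options, see [afhs_options()].
#' @return A validated `afhs_config`.
#' @export
#' @examples
#' config <- generate_config(synth_config(seed = 7, n_countries = 3))
#' config
generate_config <- function(sc, options = afhs_options()) {
  stopifnot(inherits(sc, "afhs_synth_config"))
  withr::with_seed(sc$seed, {
    countries <- load_country_table()
    if (sc$n_countries < 74) {
      countries <- countries %>%
        slice_sample(n = sc$n_countries) %>%
        arrange(.data$country_id)
    }
    countries$pop_growth_rate <- runif(nrow(countries),
                                       sc$growth_rate_range[1],
                                       sc$growth_rate_range[2])
    specs <- load_intervention_table()
    characteristics <- load_characteristics_table()

    draw <- function(lo, hi) {
      if (sc$baseline_mode == "range_midpoint") (lo + hi) / 2
      else runif(length(lo), lo, hi)
    }
    cells <- tidyr::expand_grid(country_id = countries$country_id,
                                intervention_id = specs$intervention_id) %>%
      left_join(specs[, c("intervention_id", "need_share_lo", "need_share_hi",
                          "coverage_lo", "coverage_hi")],
                by = "intervention_id")
    need_params <- tibble(country_id = cells$country_id,
                          intervention_id = cells$intervention_id,
                          need_share = draw(cells$need_share_lo,
                                            cells$need_share_hi))
    baselines <- tibble(country_id = cells$country_id,
                        intervention_id = cells$intervention_id,
                        baseline = draw(cells$coverage_lo, cells$coverage_hi))

    unit_costs <- tidyr::expand_grid(country_id = countries$country_id,
                                     level = DELIVERY_LEVELS)
    unit_costs$unit_cost <- unname(SERVICE_COST_ANCHORS[unit_costs$level]) *
      lognorm_factor(nrow(unit_costs), sc$price_dispersion)

    ingredients <- readr::read_csv(afhs_extdata("ingredients.csv"),
                                   show_col_types = FALSE, progress = FALSE)
    commodity <- ingredients$category != "service_delivery"
    ingredients$unit_price_usd[commodity] <-
      ingredients$unit_price_usd[commodity] *
      lognorm_factor(sum(commodity), sc$price_dispersion)

    programme_activities <- readr::read_csv(
      afhs_extdata("programme_activities.csv"),
      show_col_types = FALSE, progress = FALSE)

    # districts of ~500k population, ~1 primary facility per 10k population
    drivers <- tibble(
      country_id = countries$country_id,
      n_districts = pmax(1, round(countries$total_pop_2010 / 5e5 *
                                    lognorm_factor(nrow(countries),
                                                   sc$price_dispersion))),
      n_facilities = pmax(5, round(countries$total_pop_2010 / 1e4 *
                                     lognorm_factor(nrow(countries),
                                                    sc$price_dispersion))))

    afhs_config(countries = countries, interventions = specs,
                need_params = need_params, baselines = baselines,
                unit_costs = unit_costs, ingredients = ingredients,
                programme_activities = programme_activities,
                drivers = drivers, characteristics = characteristics,
                options = options)
  })
}

#' Hand-computable worked example with its expected cost cube
#'
#' A two-country, two-intervention configuration small enough to cost by
#' hand, together with the cube the documented formulas produce. The
#' expected cube is computed here from the closed forms (population x need
#' share x incremental coverage x cost per case; programme components x
#' scaling driver), independently of the scenario runner, and serves as the
#' end-to-end regression fixture.
#'
#' Both countries have zero population growth so every quantity is exact:
#' with the 2010 anchor, year `2010 + k` carries `k/5` of the coverage gap.
#'
#' @return A list with elements `config` (an `afhs_config`) and
#'   `expected_cube` (tibble of expected cell amounts).
#' @export
make_toy_worked_example <- function() {
  flag <- function() rep("observed", 2)
  countries <- tibble(
    country_id = c("alpha", "beta"), name = c("Alpha", "Beta"),
    who_region = c("AFR_E", "SEAR_D"), income_group = c("low", "middle"),
    adol_pop_2010 = c(1e5, 2e5), total_pop_2010 = c(5e5, 1e6),
    pop_growth_rate = c(0, 0),
    hiv_prev_boys = c(0.01, 0.02), hiv_prev_girls = c(0.02, 0.03),
    sex_active_10_14_boys = c(0.1, 0.1), sex_active_10_14_girls = c(0.1, 0.1),
    sex_active_15_19_boys = c(0.5, 0.5), sex_active_15_19_girls = c(0.5, 0.5),
    hiv_prev_boys_flag = flag(), hiv_prev_girls_flag = flag(),
    sex_active_10_14_boys_flag = flag(), sex_active_10_14_girls_flag = flag(),
    sex_active_15_19_boys_flag = flag(), sex_active_15_19_girls_flag = flag(),
    excluded_from_maternity = c(FALSE, FALSE),
    excluded_from_programme = c(FALSE, FALSE),
    abortion_legal = c(TRUE, TRUE), harm_reduction_permitted = c(TRUE, TRUE))

  interventions <- tibble(
    intervention_id = c("toy_universal", "toy_female"),
    number = c("t1", "t2"),
    name = c("Universal preventive service", "Female clinical service"),
    intervention_group = c("contraceptive_services", "sti_management"),
    package = c("preventive_essential", "curative_essential"),
    need_basis = c("all_adolescents", "female_adolescents"),
    sex_filter = c("both", "female"),
    requires_abortion_legal = c(FALSE, FALSE),
    requires_harm_reduction = c(FALSE, FALSE),
    costed_in = c("main_model", "main_model"),
    need_share_lo = c(0.2, 0.02), need_share_hi = c(0.8, 0.08),
    coverage_lo = c(0, 0), coverage_hi = c(0.95, 0.95),
    target_coverage = c(0.95, 0.95),
    share_hospital = c(0, 0.5), share_primary = c(1, 0.5),
    share_community = c(0, 0))

  need_params <- tibble(
    country_id = rep(c("alpha", "beta"), each = 2),
    intervention_id = rep(c("toy_universal", "toy_female"), 2),
    need_share = c(0.5, 0.04, 0.5, 0.04))
  baselines <- tibble(
    country_id = rep(c("alpha", "beta"), each = 2),
    intervention_id = rep(c("toy_universal", "toy_female"), 2),
    baseline = c(0.2, 0, 0.5, 0))
  unit_costs <- tibble(
    country_id = rep(c("alpha", "beta"), each = 3),
    level = rep(DELIVERY_LEVELS, 2),
    unit_cost = c(10, 2, 1, 12, 3, 1))
  ingredients <- tibble(
    intervention_id = c("toy_universal", "toy_universal",
                        "toy_female", "toy_female"),
    item = c("drug", "visit", "lab test", "visits"),
    category = c("drug", "service_delivery", "lab_test", "service_delivery"),
    quantity_per_case = c(2, 1, 1, 2),
    unit_price_usd = c(0.5, NA, 2, NA),
    delivery_point = "any")
  programme_activities <- tibble(
    activity_id = c("mgmt_national", "iec_campaign"),
    category = c("management", "IEC"),
    level = c("national", "national"),
    item = c("coordination", "IEC materials per 1000 adolescents"),
    quantity = c(1, 2.5), unit_price_usd = c(50000, 40),
    scaling_driver = c("per_country_year", "per_population"))
  drivers <- tibble(country_id = c("alpha", "beta"),
                    n_districts = c(2, 4), n_facilities = c(10, 20))

  config <- afhs_config(countries = countries, interventions = interventions,
                        need_params = need_params, baselines = baselines,
                        unit_costs = unit_costs, ingredients = ingredients,
                        programme_activities = programme_activities,
                        drivers = drivers)

  # Expected cube by the documented closed forms, spreadsheet-checkable.
  # Increment in year 2010+k is (k/5) * (target - baseline); cases are
  # population in need times that increment; cost is cases * cost per case.
  k <- 1:5
  years <- as.integer(2010 + k)
  row <- function(cid, region, income, iid, group, cat, pcat, amount) {
    tibble(country_id = cid, who_region = region, income_group = income,
           intervention_id = iid, intervention_group = group, year = years,
           cost_category = cat, programme_category = pcat, amount = amount)
  }
  expected <- bind_rows(
    # alpha, toy_universal: PIN 100000*0.5 = 50000; gap 0.95-0.2 = 0.75;
    # cpc commodities 2*0.5 = 1, service 1 visit * $2 primary = 2
    row("alpha", "AFR_E", "low", "toy_universal", "contraceptive_services",
        "commodities", NA, 50000 * (k / 5) * 0.75 * 1),
    row("alpha", "AFR_E", "low", "toy_universal", "contraceptive_services",
        "service_delivery", NA, 50000 * (k / 5) * 0.75 * 2),
    # beta, toy_universal: PIN 100000; gap 0.45; cpc 1 and 1 visit * $3
    row("beta", "SEAR_D", "middle", "toy_universal", "contraceptive_services",
        "commodities", NA, 100000 * (k / 5) * 0.45 * 1),
    row("beta", "SEAR_D", "middle", "toy_universal", "contraceptive_services",
        "service_delivery", NA, 100000 * (k / 5) * 0.45 * 3),
    # alpha, toy_female: PIN 50000*0.04 = 2000; gap 0.95;
    # cpc commodities 2, service 2 visits * (0.5*$10 + 0.5*$2) = 12
    row("alpha", "AFR_E", "low", "toy_female", "sti_management",
        "commodities", NA, 2000 * (k / 5) * 0.95 * 2),
    row("alpha", "AFR_E", "low", "toy_female", "sti_management",
        "service_delivery", NA, 2000 * (k / 5) * 0.95 * 12),
    # beta, toy_female: PIN 4000; service 2 visits * (0.5*$12 + 0.5*$3) = 15
    row("beta", "SEAR_D", "middle", "toy_female", "sti_management",
        "commodities", NA, 4000 * (k / 5) * 0.95 * 2),
    row("beta", "SEAR_D", "middle", "toy_female", "sti_management",
        "service_delivery", NA, 4000 * (k / 5) * 0.95 * 15),
    # programme: management $50,000 per country-year;
    # IEC 2.5 * $40 = $100 per 1000 adolescents, population constant
    row("alpha", "AFR_E", "low", "mgmt_national", "programme_activities",
        "programme", "management", rep(50000, 5)),
    row("beta", "SEAR_D", "middle", "mgmt_national", "programme_activities",
        "programme", "management", rep(50000, 5)),
    row("alpha", "AFR_E", "low", "iec_campaign", "programme_activities",
        "programme", "IEC", rep(100 * 1e5 / 1000, 5)),
    row("beta", "SEAR_D", "middle", "iec_campaign", "programme_activities",
        "programme", "IEC", rep(100 * 2e5 / 1000, 5)))

  list(config = config, expected_cube = expected)
}
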