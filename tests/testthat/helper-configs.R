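# Shared builders for unit tests.

make_country <- function(country_id = "testland", adol_pop = 1e6,
                         growth = 0.02, who_region = "AFR_E",
                         income_group = "low",
                         hiv_boys = 0.01, hiv_girls = 0.02,
                         sa = c(0.1, 0.15, 0.5, 0.55),
                         excluded_maternity = FALSE,
                         excluded_programme = FALSE,
                         abortion_legal = TRUE,
                         harm_reduction = TRUE) {
  tibble::tibble(
    country_id = country_id, name = country_id, who_region = who_region,
    income_group = income_group, adol_pop_2010 = adol_pop,
    total_pop_2010 = adol_pop / 0.21, pop_growth_rate = growth,
    hiv_prev_boys = hiv_boys, hiv_prev_girls = hiv_girls,
    sex_active_10_14_boys = sa[1], sex_active_10_14_girls = sa[2],
    sex_active_15_19_boys = sa[3], sex_active_15_19_girls = sa[4],
    hiv_prev_boys_flag = "observed", hiv_prev_girls_flag = "observed",
    sex_active_10_14_boys_flag = "observed",
    sex_active_10_14_girls_flag = "observed",
    sex_active_15_19_boys_flag = "observed",
    sex_active_15_19_girls_flag = "observed",
    excluded_from_maternity = excluded_maternity,
    excluded_from_programme = excluded_programme,
    abortion_legal = abortion_legal,
    harm_reduction_permitted = harm_reduction)
}

make_spec <- function(intervention_id = "testint",
                      need_basis = "all_adolescents",
                      need_range = c(0, 1), cov_range = c(0, 0.95),
                      target = 0.95,
                      shares = c(hospital = 0, primary = 1, community = 0),
                      sex_filter = "both",
                      requires_abortion_legal = FALSE,
                      requires_harm_reduction = FALSE,
                      costed_in = "main_model",
                      group = "contraceptive_services") {
  tibble::tibble(
    intervention_id = intervention_id, number = "1x", name = intervention_id,
    intervention_group = group, package = "preventive_essential",
    need_basis = need_basis, sex_filter = sex_filter,
    requires_abortion_legal = requires_abortion_legal,
    requires_harm_reduction = requires_harm_reduction,
    costed_in = costed_in,
    need_share_lo = need_range[1], need_share_hi = need_range[2],
    coverage_lo = cov_range[1], coverage_hi = cov_range[2],
    target_coverage = target,
    share_hospital = shares[["hospital"]],
    share_primary = shares[["primary"]],
    share_community = shares[["community"]])
}

# Restrict a config to a subset of interventions (revalidated).
shrink_config <- function(config, intervention_ids) {
  afhs_config(
    countries = config$countries,
    interventions = config$interventions[
      config$interventions$intervention_id %in% intervention_ids, ],
    need_params = config$need_params[
      config$need_params$intervention_id %in% intervention_ids, ],
    baselines = config$baselines[
      config$baselines$intervention_id %in% intervention_ids, ],
    unit_costs = config$unit_costs, ingredients = config$ingredients,
    programme_activities = config$programme_activities,
    drivers = config$drivers, characteristics = config$characteristics,
    options = config$options)
}

scale_prices <- function(config, k) {
  config$unit_costs$unit_cost <- config$unit_costs$unit_cost * k
  config$ingredients$unit_price_usd <- config$ingredients$unit_price_usd * k
  config$programme_activities$unit_price_usd <-
    config$programme_activities$unit_price_usd * k
  do.call(afhs_config, unclass(config))
}

scale_population <- function(config, k) {
  config$countries$adol_pop_2010 <- config$countries$adol_pop_2010 * k
  config$countries$total_pop_2010 <- config$countries$total_pop_2010 * k
  do.call(afhs_config, unclass(config))
}

cube_keys <- c("country_id", "who_region", "income_group", "intervention_id",
               "intervention_group", "year", "cost_category",
               "programme_category")

join_cubes <- function(a, b) {
  m <- dplyr::left_join(tibble::as_tibble(a), tibble::as_tibble(b),
                        by = cube_keys, suffix = c("_a", "_b"))
  stopifnot(!anyNA(m$amount_b))
  m
}
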