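cube_columns <- function() {
  tibble(country_id = character(), who_region = character(),
         income_group = character(), intervention_id = character(),
         intervention_group = character(), year = integer(),
         cost_category = character(), programme_category = character(),
         amount = double())
}

new_cube <- function(records) {
  cube <- bind_rows(cube_columns(), records)
  class(cube) <- unique(c("afhs_cube", class(cube)))
  cube
}

#' Cost per case of an intervention, split by cost category
#'
#' Ingredients approach: cost = quantity x price, summed over the
#' intervention's ingredient lines. Commodity lines (drugs, lab tests,
#' medical supplies) use global unit prices; service-delivery lines carry
#' visit / bed-day quantities that are priced with the country's unit cost
#' at each delivery level, weighted by the intervention's delivery-point
#' shares.
#'
#' @param spec One-row intervention tibble.
#' @param ingredients Ingredient table with columns `intervention_id`,
#'   `item`, `category`, `quantity_per_case`, `unit_price_usd`,
#'   `delivery_point`.
#' @param unit_costs Service-delivery unit costs: `country_id`, `level`,
#'   `unit_cost`.
#' @param country_id Country whose service prices to use.
#' @return Named numeric vector `c(commodities =, service_delivery =)` in
#'   US$ (2008) per case.
#' @export
cost_per_case <- function(spec, ingredients, unit_costs, country_id) {
  ing <- ingredients[ingredients$intervention_id == spec$intervention_id, ]
  is_service <- ing$category == "service_delivery"
  commodity <- ing[!is_service, ]
  if (anyNA(commodity$unit_price_usd)) {
    abort_validation(paste0("missing commodity price for intervention ",
                            spec$intervention_id))
  }
  commodities <- sum(commodity$quantity_per_case * commodity$unit_price_usd)

  visits <- sum(ing$quantity_per_case[is_service])
  shares <- c(hospital = spec$share_hospital, primary = spec$share_primary,
              community = spec$share_community)
  uc <- unit_costs[unit_costs$country_id == country_id, ]
  service <- 0
  for (level in DELIVERY_LEVELS) {
    if (shares[[level]] <= 0) next
    price <- uc$unit_cost[uc$level == level]
    if (length(price) != 1 || is.na(price)) {
      abort_validation(paste0("missing service-delivery unit cost: country '",
                              country_id, "', level '", level, "'"))
    }
    service <- service + shares[[level]] * visits * unname(price)
  }
  c(commodities = unname(commodities), service_delivery = service)
}

#' Incremental intervention cost records
#'
#' Cases to be costed in a year are the population in need multiplied by the
#' incremental coverage of the scale-up trajectory; cost records are cases
#' times the cost per case, split into commodity and service-delivery
#' categories. Countries excluded from the maternity model receive no
#' records for maternity-model interventions.
#'
#' @param country One-row country tibble.
#' @param spec One-row intervention tibble.
#' @param years Calendar years to cost.
#' @param need [population_in_need()] output for the same country,
#'   intervention and years.
#' @param traj One-row [coverage_trajectory()] for the same pair.
#' @param cpc [cost_per_case()] output for the same pair.
#' @return Cost-cube records (one row per year x cost category).
#' @export
intervention_cost <- function(country, spec, years, need, traj, cpc) {
  if (!all(need$country_id == country$country_id) ||
      !all(need$intervention_id == spec$intervention_id) ||
      traj$country_id != country$country_id ||
      traj$intervention_id != spec$intervention_id) {
    abort_validation("need/trajectory keys do not match country/intervention")
  }
  if (!setequal(need$year, years)) {
    abort_validation("need table does not cover the requested years")
  }
  if (spec$costed_in == "maternity_model" &&
      isTRUE(country$excluded_from_maternity)) {
    return(new_cube(NULL))
  }
  need <- need[order(need$year), ]
  years <- sort(years)
  inc <- incremental_coverage(traj, years)
  cases <- need$persons_in_need * inc
  records <- purrr::map_dfr(c("commodities", "service_delivery"), function(cat) {
    tibble(country_id = country$country_id, who_region = country$who_region,
           income_group = country$income_group,
           intervention_id = spec$intervention_id,
           intervention_group = spec$intervention_group,
           year = as.integer(years), cost_category = cat,
           programme_category = NA_character_,
           amount = cases * cpc[[cat]])
  })
  new_cube(records)
}

#' Programme-activity cost records
#'
#' Programme activities (management, training, supervision, IEC,
#' infrastructure and equipment) are costed from their component quantities
#' and prices, scaled by the activity's driver: once per country-year, per
#' district, per facility, or -- for IEC only -- per 1,000 adolescents of
#' the year, which makes IEC the only programme component that grows with
#' population. Somalia-type exclusions produce no records.
#'
#' @param country One-row country tibble.
#' @param activity Component rows of a single activity (columns
#'   `activity_id`, `category`, `level`, `item`, `quantity`,
#'   `unit_price_usd`, `scaling_driver`).
#' @param years Calendar years to cost.
#' @param drivers One-row tibble with `n_districts` and `n_facilities` for
#'   the country.
#' @return Cost-cube records (one row per year).
#' @export
programme_cost <- function(country, activity, years, drivers) {
  if (length(unique(activity$activity_id)) != 1 ||
      length(unique(activity$scaling_driver)) != 1) {
    abort_validation("activity rows must share one activity_id and driver")
  }
  if (isTRUE(country$excluded_from_programme)) {
    return(new_cube(NULL))
  }
  driver <- activity$scaling_driver[1]
  category <- activity$category[1]
  if (driver == "per_population" && category != "IEC") {
    abort_validation("per_population scaling is reserved for IEC activities")
  }
  base_cost <- sum(activity$quantity * activity$unit_price_usd)
  mult <- switch(driver,
    per_country_year = rep(1, length(years)),
    per_district = {
      if (is.null(drivers$n_districts) || is.na(drivers$n_districts)) {
        abort_validation(paste0("missing district count for ",
                                country$country_id))
      }
      rep(drivers$n_districts, length(years))
    },
    per_facility = {
      if (is.null(drivers$n_facilities) || is.na(drivers$n_facilities)) {
        abort_validation(paste0("missing facility count for ",
                                country$country_id))
      }
      rep(drivers$n_facilities, length(years))
    },
    per_population = project_population(country$adol_pop_2010,
                                        country$pop_growth_rate,
                                        2010, years) / 1000,
    abort_validation(paste0("unknown scaling driver: ", driver))
  )
  records <- tibble(
    country_id = country$country_id, who_region = country$who_region,
    income_group = country$income_group,
    intervention_id = activity$activity_id[1],
    intervention_group = "programme_activities",
    year = as.integer(years), cost_category = "programme",
    programme_category = category, amount = base_cost * mult)
  new_cube(records)
}
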