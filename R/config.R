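#' Model run options
#'
#' @param start_year,end_year Costed window (defaults 2011-2015).
#' @param base_year Demographic reference year for the population table.
#' @param anchor_year Year at which coverage equals the baseline (2010 by
#'   default, so the first costed year carries one fifth of the gap; 2011
#'   costs the first year at baseline).
#' @param sex_share_female Share of adolescents who are female.
#' @param age_share_10_14 Share of adolescents aged 10-14.
#' @param annualization_years Divisor used to annualize the current-spending
#'   estimate (the length of the costed window).
#' @return A named list of options.
#' @export
afhs_options <- function(start_year = 2011, end_year = 2015,
                         base_year = 2010, anchor_year = 2010,
                         sex_share_female = 0.5, age_share_10_14 = 0.5,
                         annualization_years = 5) {
  list(start_year = start_year, end_year = end_year, base_year = base_year,
       anchor_year = anchor_year, sex_share_female = sex_share_female,
       age_share_10_14 = age_share_10_14,
       annualization_years = annualization_years)
}

#' Assemble a model configuration
#'
#' Bundles all tables the scenario runner needs and validates them as a
#' whole. A configuration is a pure value: two runs of the same
#' configuration produce identical cost cubes.
#'
#' @param countries Country registry (fractions/persons, as returned by
#'   [load_country_table()]).
#' @param interventions Intervention catalogue ([load_intervention_table()]).
#' @param need_params Per country x intervention need shares: columns
#'   `country_id`, `intervention_id`, `need_share`.
#' @param baselines Per country x intervention baseline coverage: columns
#'   `country_id`, `intervention_id`, `baseline`.
#' @param unit_costs Service-delivery unit costs per country and level:
#'   columns `country_id`, `level`, `unit_cost`.
#' @param ingredients Ingredient lines per intervention.
#' @param programme_activities Programme-activity component lines.
#' @param drivers Per-country scaling drivers: `country_id`, `n_districts`,
#'   `n_facilities`.
#' @param characteristics Optional 20-row service-characteristics table.
#' @param options Options list from [afhs_options()].
#' @return An `afhs_config` object.
#' @export
afhs_config <- function(countries, interventions, need_params, baselines,
                        unit_costs, ingredients, programme_activities,
                        drivers, characteristics = NULL,
                        options = afhs_options()) {
  config <- structure(
    list(countries = countries, interventions = interventions,
         need_params = need_params, baselines = baselines,
         unit_costs = unit_costs, ingredients = ingredients,
         programme_activities = programme_activities, drivers = drivers,
         characteristics = characteristics, options = options),
    class = "afhs_config")
  validate_config(config)
  config
}

#' Validate a model configuration
#'
#' Cross-checks every table against the others: intervention invariants
#' (delivery shares summing to 1, ranges ordered), country invariants,
#' complete need-share and baseline tables with values inside the
#' intervention's admissible ranges, service unit costs for every delivery
#' level active in some intervention, driver counts for every country, the
#' per-population restriction to IEC activities, and -- when present -- the
#' 20-entry characteristics table.
#'
#' @param config An `afhs_config` object (or bare list with the same
#'   elements).
#' @return `TRUE`, invisibly; otherwise a classed error.
#' @export
validate_config <- function(config) {
  countries <- config$countries
  specs <- config$interventions
  validate_countries(countries, n_expected = nrow(countries))
  validate_interventions(specs)
  if (!is.null(config$characteristics)) {
    if (nrow(config$characteristics) != 20) {
      abort_integrity("characteristics table must hold exactly 20 entries")
    }
  }

  keys <- tidyr::expand_grid(country_id = countries$country_id,
                             intervention_id = specs$intervention_id)
  for (tbl_name in c("need_params", "baselines")) {
    tbl <- config[[tbl_name]]
    miss <- dplyr::anti_join(keys, tbl, by = c("country_id", "intervention_id"))
    if (nrow(miss) > 0) {
      abort_validation(paste0(tbl_name, " is missing ", nrow(miss),
                              " country x intervention cell(s)"))
    }
  }

  np <- left_join(config$need_params,
                  specs[, c("intervention_id", "need_share_lo", "need_share_hi")],
                  by = "intervention_id")
  bad <- np$need_share < np$need_share_lo - 1e-12 |
         np$need_share > np$need_share_hi + 1e-12
  if (any(bad)) {
    i <- which(bad)[1]
    abort_validation(paste0("need share outside admissible range for ",
                            np$country_id[i], " x ", np$intervention_id[i]))
  }

  bl <- left_join(config$baselines,
                  specs[, c("intervention_id", "coverage_lo", "coverage_hi")],
                  by = "intervention_id")
  bad <- bl$baseline < bl$coverage_lo - 1e-12 |
         bl$baseline > bl$coverage_hi + 1e-12
  if (any(bad)) {
    i <- which(bad)[1]
    abort_validation(paste0("baseline coverage outside admissible range for ",
                            bl$country_id[i], " x ", bl$intervention_id[i]))
  }

  active_levels <- DELIVERY_LEVELS[c(any(specs$share_hospital > 0),
                                     any(specs$share_primary > 0),
                                     any(specs$share_community > 0))]
  uc <- config$unit_costs
  if (any(uc$unit_cost < 0, na.rm = TRUE)) {
    abort_validation("service unit costs must be non-negative")
  }
  for (level in active_levels) {
    have <- uc$country_id[uc$level == level & !is.na(uc$unit_cost)]
    miss <- setdiff(countries$country_id, have)
    if (length(miss) > 0) {
      abort_validation(paste0("missing service-delivery unit cost: country '",
                              miss[1], "', level '", level, "'"))
    }
  }

  ing <- config$ingredients
  if (any(ing$quantity_per_case < 0)) {
    abort_validation("ingredient quantities must be non-negative")
  }
  commodity <- ing[ing$category != "service_delivery", ]
  if (anyNA(commodity$unit_price_usd) || any(commodity$unit_price_usd < 0)) {
    abort_validation("commodity ingredient lines need non-negative prices")
  }
  miss <- setdiff(specs$intervention_id, unique(ing$intervention_id))
  if (length(miss) > 0) {
    abort_validation(paste0("no ingredient lines for intervention(s): ",
                            paste(miss, collapse = ", ")))
  }

  pa <- config$programme_activities
  if (nrow(pa) > 0) {
    if (!all(pa$category %in% PROGRAMME_CATEGORIES)) {
      abort_validation("unknown programme-activity category")
    }
    off <- pa$scaling_driver == "per_population" & pa$category != "IEC"
    if (any(off)) {
      abort_validation("per_population scaling is reserved for IEC activities")
    }
    per_act <- distinct(pa[, c("activity_id", "scaling_driver")])
    if (anyDuplicated(per_act$activity_id)) {
      abort_validation("an activity_id mixes different scaling drivers")
    }
    miss <- setdiff(countries$country_id, config$drivers$country_id)
    if (length(miss) > 0) {
      abort_validation(paste0("missing driver counts for country: ", miss[1]))
    }
  }
  invisible(TRUE)
}

#' @export
print.afhs_config <- function(x, ...) {
  cat("<afhs_config>\n")
  cat("  countries:            ", nrow(x$countries), "\n")
  cat("  interventions:        ", nrow(x$interventions), "\n")
  cat("  programme activities: ",
      length(unique(x$programme_activities$activity_id)), "\n")
  cat("  window:               ", x$options$start_year, "-",
      x$options$end_year, " (anchor ", x$options$anchor_year, ")\n", sep = "")
  invisible(x)
}

config_tables <- c("countries", "interventions", "need_params", "baselines",
                   "unit_costs", "ingredients", "programme_activities",
                   "drivers", "characteristics")

#' Write a configuration to a directory of CSV files
#'
#' One CSV per table plus an `options.csv` key-value file. Writing the same
#' configuration twice produces byte-identical files.
#'
#' @param config An `afhs_config` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_config <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tbl in config_tables) {
    if (is.null(config[[tbl]])) next
    readr::write_csv(config[[tbl]], file.path(dir, paste0(tbl, ".csv")),
                     progress = FALSE)
  }
  opts <- config$options
  readr::write_csv(
    tibble(key = names(opts),
           value = vapply(opts, function(v) format(v, digits = 15),
                          character(1))),
    file.path(dir, "options.csv"), progress = FALSE)
  invisible(dir)
}

#' Read a configuration from a directory written by [write_config()]
#'
#' @param dir Directory holding the configuration CSVs.
#' @return An `afhs_config` object (validated on construction).
#' @export
read_config <- function(dir) {
  read_tbl <- function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) return(NULL)
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  opts_raw <- read_tbl("options")
  opts <- afhs_options()
  for (i in seq_len(nrow(opts_raw))) {
    opts[[opts_raw$key[i]]] <- as.numeric(opts_raw$value[i])
  }
  afhs_config(
    countries = read_tbl("countries"), interventions = read_tbl("interventions"),
    need_params = read_tbl("need_params"), baselines = read_tbl("baselines"),
    unit_costs = read_tbl("unit_costs"), ingredients = read_tbl("ingredients"),
    programme_activities = read_tbl("programme_activities"),
    drivers = read_tbl("drivers"), characteristics = read_tbl("characteristics"),
    options = opts)
}
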