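#' Run a full costing scenario
#'
#' Executes the whole pipeline for every eligible country x intervention x
#' year cell of a configuration: population projection and splitting,
#' population in need, linear coverage trajectories, cost per case,
#' incremental intervention costs, and programme-activity costs. The result
#' is deterministic given the configuration -- no randomness is involved at
#' this stage -- and any validation failure aborts before any output is
#' produced.
#'
#' @param config An `afhs_config` object.
#' @param mode `"incremental"` (scale up from observed baselines) or
#'   `"from_zero"` (baselines forced to 0; used to back out current
#'   spending).
#' @return An `afhs_scenario`: list with elements `mode`, `cube` (the cost
#'   cube, one row per cell), and `metadata` (configuration hash and anchor
#'   convention).
#' @export
#' @examples
#' \donttest{
#' config <- generate_config(synth_config(seed = 1, n_countries = 5))
#' sc <- run_scenario(config, mode = "incremental")
#' sum(sc$cube$amount)
#' }
run_scenario <- function(config, mode = c("incremental", "from_zero")) {
  mode <- match.arg(mode)
  validate_config(config)
  opts <- config$options
  years <- seq(opts$start_year, opts$end_year)
  countries <- config$countries
  specs <- config$interventions

  need_key <- paste(config$need_params$country_id,
                    config$need_params$intervention_id)
  need_lookup <- stats::setNames(config$need_params$need_share, need_key)
  base_key <- paste(config$baselines$country_id,
                    config$baselines$intervention_id)
  base_lookup <- stats::setNames(config$baselines$baseline, base_key)

  pieces <- vector("list", nrow(countries) * nrow(specs))
  k <- 0L
  for (ci in seq_len(nrow(countries))) {
    country <- countries[ci, ]
    slices <- population_slices(country, years,
                                sex_share_female = opts$sex_share_female,
                                age_share_10_14 = opts$age_share_10_14)
    for (si in seq_len(nrow(specs))) {
      spec <- specs[si, ]
      key <- paste(country$country_id, spec$intervention_id)
      need <- population_in_need(country, spec, years,
                                 need_share = need_lookup[[key]],
                                 sex_share_female = opts$sex_share_female,
                                 age_share_10_14 = opts$age_share_10_14,
                                 slices = slices)
      traj <- coverage_trajectory(country$country_id, spec$intervention_id,
                                  baseline = base_lookup[[key]],
                                  target = spec$target_coverage,
                                  mode = mode,
                                  start_year = opts$start_year,
                                  end_year = opts$end_year,
                                  anchor_year = opts$anchor_year)
      cpc <- cost_per_case(spec, config$ingredients, config$unit_costs,
                           country$country_id)
      k <- k + 1L
      pieces[[k]] <- intervention_cost(country, spec, years, need, traj, cpc)
    }
  }

  activities <- split(config$programme_activities,
                      config$programme_activities$activity_id)
  prog <- vector("list", nrow(countries) * length(activities))
  k <- 0L
  for (ci in seq_len(nrow(countries))) {
    country <- countries[ci, ]
    drv <- config$drivers[config$drivers$country_id == country$country_id, ]
    for (act in activities) {
      k <- k + 1L
      prog[[k]] <- programme_cost(country, act, years, drv)
    }
  }

  cube <- new_cube(bind_rows(bind_rows(pieces), bind_rows(prog)))
  structure(
    list(mode = mode, cube = cube,
         metadata = list(config_hash = rlang::hash(unclass(config)),
                         anchor_year = opts$anchor_year,
                         years = years)),
    class = "afhs_scenario")
}

#' @export
print.afhs_scenario <- function(x, ...) {
  cat("<afhs_scenario> mode =", x$mode, "\n")
  cat("  cells:", nrow(x$cube), "\n")
  cat("  total: US$", format(sum(x$cube$amount), big.mark = ","), "\n")
  invisible(x)
}

#' Estimate current spending from paired scenario runs
#'
#' Running the model from 0% starting coverage costs the full service
#' volume; the incremental run costs only the volume above current
#' coverage. Their cell-wise difference is the volume already covered
#' today, i.e. an estimate of what is currently being spent on these
#' services. Programme-activity cells are identical in both modes, so their
#' difference is zero.
#'
#' @param inc Incremental-mode `afhs_scenario`.
#' @param fz From-zero-mode `afhs_scenario` of the same configuration.
#' @return A cost cube of non-negative cell-wise differences, with an
#'   `annual_average` attribute (total divided by the number of costed
#'   years).
#' @export
current_spending <- function(inc, fz) {
  if (inc$mode != "incremental" || fz$mode != "from_zero") {
    abort_validation("current_spending() needs an incremental and a from_zero run")
  }
  if (!identical(inc$metadata$config_hash, fz$metadata$config_hash)) {
    abort_validation("scenario runs come from different configurations")
  }
  keys <- c("country_id", "who_region", "income_group", "intervention_id",
            "intervention_group", "year", "cost_category",
            "programme_category")
  merged <- left_join(fz$cube, inc$cube, by = keys,
                      suffix = c("_fz", "_inc"))
  if (anyNA(merged$amount_inc)) {
    abort_validation("scenario cubes do not share the same cells")
  }
  diff <- merged$amount_fz - merged$amount_inc
  if (any(diff < -1e-6 * pmax(1, merged$amount_fz))) {
    abort_validation("from_zero cube is not cell-wise >= incremental cube")
  }
  cube <- merged
  cube$amount <- pmax(0, diff)
  cube$amount_fz <- NULL
  cube$amount_inc <- NULL
  cube <- new_cube(cube)
  attr(cube, "annual_average") <- sum(cube$amount) /
    length(inc$metadata$years)
  cube
}

#' Aggregate a cost cube into a reporting view
#'
#' Sums the cube over any subset of the reporting keys (year, WHO region,
#' intervention group, cost category, income group). Every view is an exact
#' partition of the grand total, and the percentage shares sum to 100.
#'
#' @param cube A cost cube (from a scenario run or [current_spending()]).
#' @param by Character vector of grouping keys, a subset of
#'   `c("year", "who_region", "intervention_group", "cost_category",
#'   "income_group", "intervention_id", "programme_category", "country_id")`.
#' @return A tibble with the grouping keys, `total` (US$ 2008) and
#'   `share_pct`.
#' @export
#' @examples
#' \donttest{
#' config <- generate_config(synth_config(seed = 1, n_countries = 5))
#' sc <- run_scenario(config)
#' aggregate_costs(sc$cube, by = c("year", "cost_category"))
#' }
aggregate_costs <- function(cube, by) {
  allowed <- c("year", "who_region", "intervention_group", "cost_category",
               "income_group", "intervention_id", "programme_category",
               "country_id")
  bad <- setdiff(by, allowed)
  if (length(bad) > 0) {
    abort_validation(paste0("unknown grouping key(s): ",
                            paste(bad, collapse = ", ")))
  }
  out <- cube %>%
    group_by(dplyr::across(dplyr::all_of(by))) %>%
    summarise(total = sum(.data$amount), .groups = "drop")
  out$share_pct <- 100 * out$total / sum(out$total)
  out
}

#' Per-year population denominators of a configuration
#'
#' @param config An `afhs_config` object.
#' @return Tibble with `year`, `adol_pop`, `total_pop` summed over the
#'   configuration's countries.
#' @export
population_denominators <- function(config) {
  opts <- config$options
  years <- seq(opts$start_year, opts$end_year)
  purrr::map_dfr(years, function(y) {
    tibble(
      year = as.integer(y),
      adol_pop = sum(project_population(config$countries$adol_pop_2010,
                                        config$countries$pop_growth_rate,
                                        opts$base_year, y)),
      total_pop = sum(project_population(config$countries$total_pop_2010,
                                         config$countries$pop_growth_rate,
                                         opts$base_year, y)))
  })
}

#' Per-adolescent and per-capita cost by year
#'
#' @param cube A cost cube.
#' @param populations Tibble with columns `year`, `adol_pop`, `total_pop`
#'   (see [population_denominators()]).
#' @return Tibble with `year`, `total`, `per_adolescent`, `per_capita`
#'   (US$ 2008).
#' @export
per_head_metrics <- function(cube, populations) {
  if (any(populations$adol_pop <= 0) || any(populations$total_pop <= 0)) {
    abort_validation("population denominators must be positive")
  }
  totals <- cube %>%
    group_by(year = .data$year) %>%
    summarise(total = sum(.data$amount), .groups = "drop")
  out <- left_join(totals, populations, by = "year")
  if (anyNA(out$adol_pop)) {
    abort_validation("population denominators missing for some cube years")
  }
  out %>%
    mutate(per_adolescent = .data$total / .data$adol_pop,
           per_capita = .data$total / .data$total_pop) %>%
    select("year", "total", "per_adolescent", "per_capita")
}

#' Write a cost cube as tidy CSV
#'
#' One row per cube cell, raw unformatted numbers; identical cubes write
#' byte-identical files.
#'
#' @param cube A cost cube.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  readr::write_csv(as_tibble(cube), path, progress = FALSE)
  invisible(path)
}
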