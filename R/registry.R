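#' Load and validate the country registry
#'
#' Reads the country configuration table that parameterizes the whole model:
#' WHO region, income group, adolescent population in 2010, HIV prevalence by
#' sex, sexual-activity rates by age band and sex (each with a flag recording
#' whether the value is observed or a regional/global average), the
#' maternity-model and programme-costing exclusions, and the legality flags
#' for abortion services and harm reduction.
#'
#' The packaged registry covers the 74 high-burden and least-developed
#' countries of the model. Percentages in the file are converted to
#' fractions, and populations (stored in thousands) to persons.
#'
#' @param path Path to a `countries.csv` file. Defaults to the packaged
#'   74-country registry.
#' @param n_expected Number of countries the file must contain (74 for the
#'   full registry; reduced synthetic registries pass their own count).
#' @return A tibble with one row per country, populations in persons and all
#'   rates as fractions in `[0, 1]`.
#' @export
#' @examples
#' countries <- load_country_table()
#' nrow(countries)
#' countries[countries$country_id == "kenya", c("adol_pop_2010", "hiv_prev_boys")]
load_country_table <- function(path = afhs_extdata("countries.csv"),
                               n_expected = 74) {
  if (!file.exists(path)) {
    abort_schema(paste0("country table not found: ", path))
  }
  raw <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_integrity(paste0("unreadable country table: ",
                                               conditionMessage(e)))
  )
  required <- c("country_id", "name", "who_region", "income_group",
                "adol_pop_2010_thousands", "total_pop_2010_thousands",
                "pop_growth_rate",
                paste0(RATE_FIELDS, "_pct"), paste0(RATE_FIELDS, "_flag"),
                "excluded_from_maternity", "excluded_from_programme",
                "abortion_legal", "harm_reduction_permitted")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_schema(paste0("country table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(raw) != n_expected) {
    abort_integrity(paste0("country registry must hold exactly ", n_expected,
                           " countries, found ", nrow(raw)))
  }

  countries <- raw %>%
    mutate(
      adol_pop_2010 = .data$adol_pop_2010_thousands * 1000,
      total_pop_2010 = .data$total_pop_2010_thousands * 1000
    ) %>%
    select(-"adol_pop_2010_thousands", -"total_pop_2010_thousands")
  for (f in RATE_FIELDS) {
    countries[[f]] <- countries[[paste0(f, "_pct")]] / 100
    countries[[paste0(f, "_pct")]] <- NULL
  }
  countries <- countries[, c("country_id", "name", "who_region",
                             "income_group", "adol_pop_2010",
                             "total_pop_2010", "pop_growth_rate",
                             RATE_FIELDS, paste0(RATE_FIELDS, "_flag"),
                             "excluded_from_maternity",
                             "excluded_from_programme", "abortion_legal",
                             "harm_reduction_permitted")]
  validate_countries(countries, n_expected = n_expected)
  countries
}

RATE_FIELDS <- c("hiv_prev_boys", "hiv_prev_girls",
                 "sex_active_10_14_boys", "sex_active_10_14_girls",
                 "sex_active_15_19_boys", "sex_active_15_19_girls")

#' Validate a loaded country table
#'
#' @param countries Tibble as returned by [load_country_table()].
#' @param n_expected Expected number of rows.
#' @return The table, invisibly, if valid; otherwise a classed error.
#' @keywords internal
validate_countries <- function(countries, n_expected = 74) {
  if (nrow(countries) != n_expected) {
    abort_integrity(paste0("expected ", n_expected, " countries, found ",
                           nrow(countries)))
  }
  if (anyDuplicated(countries$country_id)) {
    abort_validation("duplicate country_id in country registry")
  }
  bad_region <- setdiff(unique(countries$who_region), WHO_REGIONS)
  if (length(bad_region) > 0) {
    abort_validation(paste0("unknown WHO region label(s): ",
                            paste(bad_region, collapse = ", ")))
  }
  if (!all(countries$income_group %in% c("low", "middle"))) {
    abort_validation("income_group must be 'low' or 'middle'")
  }
  if (any(countries$adol_pop_2010 <= 0) || any(countries$total_pop_2010 <= 0)) {
    abort_validation("populations must be positive")
  }
  if (any(countries$pop_growth_rate <= -1)) {
    abort_validation("pop_growth_rate must be greater than -1")
  }
  for (f in RATE_FIELDS) {
    v <- countries[[f]]
    if (anyNA(v)) next # imputable; impute_field() fills these
    bad <- which(v < 0 | v > 1)
    if (length(bad) > 0) {
      abort_validation(paste0("fraction out of [0, 1]: field '", f,
                              "', country '",
                              countries$country_id[bad[1]], "'"))
    }
    flags <- countries[[paste0(f, "_flag")]]
    if (!all(flags %in% IMPUTATION_FLAGS)) {
      abort_validation(paste0("invalid imputation flag for field '", f, "'"))
    }
  }
  invisible(countries)
}

#' Fill missing country values with population-weighted averages
#'
#' Countries missing a value for `field` receive the adolescent-population-
#' weighted mean of the observed values in their WHO region; if a region has
#' no observed value at all, the population-weighted global mean over all
#' countries is used instead. Imputation flags are updated to
#' `regional_avg` or `global_avg` accordingly. Applying the function twice
#' is a no-op (imputation is idempotent).
#'
#' @param countries Country tibble (fractions, persons), possibly with `NA`s
#'   in `field`.
#' @param field One of the rate fields, e.g. `"hiv_prev_boys"`.
#' @return The country tibble with `field` complete.
#' @export
impute_field <- function(countries, field) {
  if (!field %in% RATE_FIELDS) {
    abort_validation(paste0("unknown imputable field: ", field))
  }
  v <- countries[[field]]
  if (!anyNA(v)) {
    return(countries)
  }
  obs <- !is.na(v)
  if (!any(obs)) {
    abort_validation(paste0("no observed values anywhere for field ", field))
  }
  w <- countries$adol_pop_2010
  global_mean <- sum(v[obs] * w[obs]) / sum(w[obs])
  flag_col <- paste0(field, "_flag")
  for (i in which(!obs)) {
    same <- obs & countries$who_region == countries$who_region[i]
    if (any(same)) {
      countries[[field]][i] <- sum(v[same] * w[same]) / sum(w[same])
      countries[[flag_col]][i] <- "regional_avg"
    } else {
      countries[[field]][i] <- global_mean
      countries[[flag_col]][i] <- "global_avg"
    }
  }
  countries
}

#' Load and validate the intervention catalogue
#'
#' Reads the table of costable health-service interventions: package
#' membership, reporting group, population-in-need basis and admissible
#' need-share range, current-coverage range, scale-up target (95% for all
#' services except opioid substitution therapy at 50%), delivery-point
#' shares (hospital / primary facility / community), sex filter, legality
#' requirements, and whether the row is costed in the main or the maternity
#' model. Percentages are converted to fractions.
#'
#' @param path Path to an `interventions.csv` file. Defaults to the packaged
#'   catalogue of 19 costable service rows in 8 reporting groups.
#' @return A tibble with one row per costable intervention.
#' @export
#' @examples
#' specs <- load_intervention_table()
#' specs[specs$intervention_id == "anc",
#'       c("share_hospital", "share_primary", "share_community")]
load_intervention_table <- function(path = afhs_extdata("interventions.csv")) {
  if (!file.exists(path)) {
    abort_schema(paste0("intervention table not found: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("intervention_id", "number", "name", "intervention_group",
                "package", "need_basis", "need_lo_pct", "need_hi_pct",
                "cov_lo_pct", "cov_hi_pct", "target_coverage_pct",
                "share_hospital_pct", "share_primary_pct",
                "share_community_pct", "sex_filter",
                "requires_abortion_legal", "requires_harm_reduction",
                "costed_in")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_schema(paste0("intervention table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  specs <- raw %>%
    mutate(
      need_share_lo = .data$need_lo_pct / 100,
      need_share_hi = .data$need_hi_pct / 100,
      coverage_lo = .data$cov_lo_pct / 100,
      coverage_hi = .data$cov_hi_pct / 100,
      target_coverage = .data$target_coverage_pct / 100,
      share_hospital = .data$share_hospital_pct / 100,
      share_primary = .data$share_primary_pct / 100,
      share_community = .data$share_community_pct / 100
    ) %>%
    select(-dplyr::ends_with("_pct"))
  validate_interventions(specs)
  specs
}

#' Validate a loaded intervention table
#' @param specs Tibble as returned by [load_intervention_table()].
#' @return The table, invisibly, if valid.
#' @keywords internal
validate_interventions <- function(specs) {
  if (anyDuplicated(specs$intervention_id)) {
    abort_validation("duplicate intervention_id in intervention table")
  }
  if (!all(specs$need_basis %in% NEED_BASES)) {
    abort_validation("unknown need_basis in intervention table")
  }
  if (!all(specs$sex_filter %in% c("both", "female"))) {
    abort_validation("sex_filter must be 'both' or 'female'")
  }
  if (!all(specs$costed_in %in% c("main_model", "maternity_model"))) {
    abort_validation("costed_in must be 'main_model' or 'maternity_model'")
  }
  share_sum <- specs$share_hospital + specs$share_primary + specs$share_community
  bad <- which(abs(share_sum - 1) > 1e-9)
  if (length(bad) > 0) {
    abort_validation(paste0("delivery shares do not sum to 1 for: ",
                            paste(specs$intervention_id[bad], collapse = ", ")))
  }
  for (col in c("need_share_lo", "need_share_hi", "coverage_lo",
                "coverage_hi", "target_coverage")) {
    if (any(specs[[col]] < 0 | specs[[col]] > 1)) {
      abort_validation(paste0(col, " outside [0, 1]"))
    }
  }
  if (any(specs$need_share_lo > specs$need_share_hi)) {
    abort_validation("need share range has lo > hi")
  }
  if (any(specs$coverage_lo > specs$coverage_hi)) {
    abort_validation("coverage range has lo > hi")
  }
  invisible(specs)
}

#' Load the characteristics of adolescent-friendly health services
#'
#' The 20 service characteristics, grouped under the five quality-of-care
#' dimensions (equitable, accessible, acceptable, appropriate, effective),
#' that define the programme activities of the model.
#'
#' @param path Path to a `characteristics.csv` file.
#' @return A tibble with columns `number`, `dimension`, `text`.
#' @export
load_characteristics_table <- function(path = afhs_extdata("characteristics.csv")) {
  if (!file.exists(path)) {
    abort_schema(paste0("characteristics table not found: ", path))
  }
  chars <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("number", "dimension", "text"), names(chars))
  if (length(missing) > 0) {
    abort_schema(paste0("characteristics table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(chars) != 20 || !setequal(chars$number, 1:20)) {
    abort_integrity("characteristics table must hold exactly entries 1-20")
  }
  if (!all(chars$dimension %in% QUALITY_DIMENSIONS)) {
    abort_validation("unknown quality dimension in characteristics table")
  }
  chars
}

#' Packaged model registry
#'
#' Convenience loader for the packaged country registry, intervention
#' catalogue and service characteristics.
#'
#' @return A list with elements `countries`, `interventions`,
#'   `characteristics`.
#' @export
default_registry <- function() {
  list(
    countries = load_country_table(),
    interventions = load_intervention_table(),
    characteristics = load_characteristics_table()
  )
}
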