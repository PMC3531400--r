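#' Project a population forward with constant geometric growth
#'
#' Epidemiological risk is held constant over the projection window, so the
#' population in need changes only through population growth:
#' `persons * (1 + growth_rate)^(to_year - from_year)`.
#'
#' @param persons Base population count (may be fractional).
#' @param growth_rate Annual growth rate as a fraction (> -1).
#' @param from_year Calendar year of the base count.
#' @param to_year Calendar year(s) to project to; must not precede
#'   `from_year` (no back-projection).
#' @return Projected population, vectorized over `to_year`.
#' @export
#' @examples
#' project_population(100, 0.02, 2010, 2012) # 104.04
project_population <- function(persons, growth_rate, from_year, to_year) {
  if (any(growth_rate <= -1)) {
    abort_validation("growth_rate must be greater than -1")
  }
  if (any(to_year < from_year)) {
    abort_validation("cannot project backwards: to_year precedes from_year")
  }
  persons * (1 + growth_rate)^(to_year - from_year)
}

#' Split an age-band total into sex-by-band slices
#'
#' Splits a 10-19 total into the four sex (male/female) by age band
#' (10-14/15-19) slices using the given shares, reconciling with the
#' largest-remainder method so the slices sum exactly to the input count.
#'
#' @param persons Total 10-19 population.
#' @param sex_shares Named numeric `c(male = , female = )` summing to 1.
#' @param age_shares Named numeric `c("10_14" = , "15_19" = )` summing to 1.
#' @return A tibble with columns `sex`, `age_band`, `persons` (4 rows).
#' @export
#' @examples
#' split_population(1000, c(male = 0.52, female = 0.48))
split_population <- function(persons,
                             sex_shares = c(male = 0.5, female = 0.5),
                             age_shares = c("10_14" = 0.5, "15_19" = 0.5)) {
  if (abs(sum(sex_shares) - 1) > 1e-9 || abs(sum(age_shares) - 1) > 1e-9) {
    abort_validation("sex and age shares must each sum to 1")
  }
  if (any(sex_shares < 0) || any(age_shares < 0)) {
    abort_validation("shares must be non-negative")
  }
  sex <- rep(c("male", "female"), each = 2)
  band <- rep(c("10_14", "15_19"), times = 2)
  raw <- persons * sex_shares[sex] * age_shares[band]
  base <- floor(raw)
  frac <- raw - base
  remainder <- persons - sum(base)
  units <- floor(remainder + 1e-9)
  ord <- order(frac, decreasing = TRUE)
  out <- base
  if (units > 0) {
    out[ord[seq_len(min(units, 4))]] <- out[ord[seq_len(min(units, 4))]] + 1
  }
  leftover <- remainder - units
  if (abs(leftover) > 1e-12) {
    # fractional totals: park the residual on the next cell in remainder order
    idx <- ord[min(units + 1, 4)]
    out[idx] <- out[idx] + leftover
  }
  tibble(sex = sex, age_band = band, persons = unname(out))
}

#' Sex-by-band population slices for a country and set of years
#'
#' Projects the 2010 adolescent population of a country to each requested
#' year and splits it into sex-by-age-band slices.
#'
#' @param country A one-row country tibble (or equivalent list).
#' @param years Calendar years (2010-2015).
#' @param sex_share_female Share of adolescents who are female.
#' @param age_share_10_14 Share of adolescents aged 10-14.
#' @return Tibble with columns `country_id`, `year`, `sex`, `age_band`,
#'   `persons`.
#' @export
population_slices <- function(country, years,
                              sex_share_female = 0.5,
                              age_share_10_14 = 0.5) {
  sex_shares <- c(male = 1 - sex_share_female, female = sex_share_female)
  age_shares <- c("10_14" = age_share_10_14, "15_19" = 1 - age_share_10_14)
  purrr::map_dfr(years, function(y) {
    total <- project_population(country$adol_pop_2010,
                                country$pop_growth_rate, 2010, y)
    sl <- split_population(total, sex_shares, age_shares)
    tibble(country_id = country$country_id, year = y,
           sex = sl$sex, age_band = sl$age_band, persons = sl$persons)
  })
}

# Eligible population for an intervention given one year's slices:
# applies the sex filter, then the basis weighting (sexual-activity rates by
# band and sex, HIV prevalence by sex, or none).
eligible_population <- function(country, spec, slices_year) {
  sexes <- if (identical(spec$sex_filter, "female")) "female" else c("male", "female")
  sl <- slices_year[slices_year$sex %in% sexes, ]
  basis <- spec$need_basis
  if (basis %in% c("all_adolescents", "condition_share", "female_adolescents")) {
    return(sum(sl$persons))
  }
  if (basis == "sexually_active") {
    rate <- function(sex, band) {
      col <- paste0("sex_active_", band, "_", if (sex == "male") "boys" else "girls")
      country[[col]]
    }
    r <- mapply(rate, sl$sex, sl$age_band)
    return(sum(sl$persons * r))
  }
  if (basis == "hiv_positive") {
    prev <- ifelse(sl$sex == "male", country$hiv_prev_boys, country$hiv_prev_girls)
    return(sum(sl$persons * prev))
  }
  abort_validation(paste0("unknown need basis: ", basis))
}

#' Population in need of an intervention
#'
#' Computes the number of adolescents in need of an intervention in each
#' requested year: the eligible population (after the sex filter and the
#' basis weighting -- sexual-activity rates, HIV prevalence, or none)
#' multiplied by the country's need share. The need share must lie within
#' the intervention's admissible range. When the intervention requires a
#' legal basis (abortion services, harm reduction) and the country's flag is
#' off, the population in need is zero.
#'
#' @param country One-row country tibble.
#' @param spec One-row intervention tibble.
#' @param years Calendar years.
#' @param need_share Need share for this country and intervention, a
#'   fraction within the intervention's `need_share_lo`..`need_share_hi`.
#' @param sex_share_female,age_share_10_14 Demographic split shares.
#' @param slices Optional precomputed [population_slices()] output covering
#'   `years` (used by the scenario runner to avoid recomputation).
#' @return Tibble with columns `country_id`, `intervention_id`, `year`,
#'   `persons_in_need`, `basis_used`.
#' @export
population_in_need <- function(country, spec, years, need_share,
                               sex_share_female = 0.5,
                               age_share_10_14 = 0.5,
                               slices = NULL) {
  if (need_share < spec$need_share_lo - 1e-12 ||
      need_share > spec$need_share_hi + 1e-12) {
    abort_validation(paste0(
      "need share ", need_share, " for ", country$country_id, " x ",
      spec$intervention_id, " outside admissible range [",
      spec$need_share_lo, ", ", spec$need_share_hi, "]"))
  }
  blocked <-
    (isTRUE(spec$requires_abortion_legal) && !isTRUE(country$abortion_legal)) ||
    (isTRUE(spec$requires_harm_reduction) && !isTRUE(country$harm_reduction_permitted))
  if (is.null(slices)) {
    slices <- population_slices(country, years, sex_share_female,
                                age_share_10_14)
  }
  pin <- vapply(years, function(y) {
    if (blocked) return(0)
    eligible_population(country, spec, slices[slices$year == y, ]) * need_share
  }, numeric(1))
  tibble(country_id = country$country_id,
         intervention_id = spec$intervention_id,
         year = years,
         persons_in_need = pin,
         basis_used = spec$need_basis)
}
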