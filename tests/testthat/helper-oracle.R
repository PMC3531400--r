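# Independent naive oracle: recomputes a scenario's grand total with flat
# base-R loops over country x intervention x year, sharing no code with the
# engine. Used to check cube additivity/conservation.

oracle_split <- function(pop, f_share, young_share) {
  # male_10_14, male_15_19, female_10_14, female_15_19 with
  # largest-remainder reconciliation; ties and fractional residue go to the
  # earlier cell in that order.
  raw <- c(pop * (1 - f_share) * young_share,
           pop * (1 - f_share) * (1 - young_share),
           pop * f_share * young_share,
           pop * f_share * (1 - young_share))
  lo <- floor(raw)
  rem <- pop - sum(lo)
  units <- floor(rem + 1e-9)
  ord <- order(raw - lo, decreasing = TRUE)
  if (units > 0) {
    for (i in seq_len(min(units, 4))) lo[ord[i]] <- lo[ord[i]] + 1
  }
  left <- rem - units
  if (abs(left) > 1e-12) {
    lo[ord[min(units + 1, 4)]] <- lo[ord[min(units + 1, 4)]] + left
  }
  lo
}

oracle_total <- function(config, mode = "incremental") {
  opts <- config$options
  years <- opts$start_year:opts$end_year
  span <- opts$end_year - opts$anchor_year
  co <- as.data.frame(config$countries)
  sp <- as.data.frame(config$interventions)
  np <- as.data.frame(config$need_params)
  bl <- as.data.frame(config$baselines)
  uc <- as.data.frame(config$unit_costs)
  ing <- as.data.frame(config$ingredients)
  pa <- as.data.frame(config$programme_activities)
  dr <- as.data.frame(config$drivers)

  total <- 0
  for (i in seq_len(nrow(co))) {
    c_row <- co[i, ]
    for (j in seq_len(nrow(sp))) {
      s_row <- sp[j, ]
      if (s_row$costed_in == "maternity_model" && c_row$excluded_from_maternity) next
      share <- np$need_share[np$country_id == c_row$country_id &
                             np$intervention_id == s_row$intervention_id]
      b <- bl$baseline[bl$country_id == c_row$country_id &
                       bl$intervention_id == s_row$intervention_id]
      if (mode == "from_zero") b <- 0
      blocked <- (s_row$requires_abortion_legal && !c_row$abortion_legal) ||
                 (s_row$requires_harm_reduction && !c_row$harm_reduction_permitted)
      # cost per case
      lines <- ing[ing$intervention_id == s_row$intervention_id, ]
      comm <- sum(lines$quantity_per_case[lines$category != "service_delivery"] *
                  lines$unit_price_usd[lines$category != "service_delivery"])
      visits <- sum(lines$quantity_per_case[lines$category == "service_delivery"])
      svc <- 0
      for (lvl in c("hospital", "primary", "community")) {
        sh <- s_row[[paste0("share_", lvl)]]
        if (sh > 0) {
          svc <- svc + sh * visits *
            uc$unit_cost[uc$country_id == c_row$country_id & uc$level == lvl]
        }
      }
      for (y in years) {
        pop <- c_row$adol_pop_2010 * (1 + c_row$pop_growth_rate)^(y - 2010)
        cells <- oracle_split(pop, opts$sex_share_female, opts$age_share_10_14)
        male <- s_row$sex_filter == "both"
        elig <- switch(s_row$need_basis,
          all_adolescents = ,
          condition_share = sum(cells[c(if (male) 1:2, 3:4)]),
          female_adolescents = cells[3] + cells[4],
          sexually_active = {
            e <- cells[3] * c_row$sex_active_10_14_girls +
                 cells[4] * c_row$sex_active_15_19_girls
            if (male) e <- e + cells[1] * c_row$sex_active_10_14_boys +
                             cells[2] * c_row$sex_active_15_19_boys
            e
          },
          hiv_positive = {
            e <- (cells[3] + cells[4]) * c_row$hiv_prev_girls
            if (male) e <- e + (cells[1] + cells[2]) * c_row$hiv_prev_boys
            e
          })
        pin <- if (blocked) 0 else elig * share
        cov <- b + (y - opts$anchor_year) / span * (s_row$target_coverage - b)
        inc <- max(0, cov - b)
        total <- total + pin * inc * (comm + svc)
      }
    }
    # programme activities
    if (!c_row$excluded_from_programme && nrow(pa) > 0) {
      d_row <- dr[dr$country_id == c_row$country_id, ]
      for (aid in unique(pa$activity_id)) {
        a <- pa[pa$activity_id == aid, ]
        base <- sum(a$quantity * a$unit_price_usd)
        for (y in years) {
          mult <- switch(a$scaling_driver[1],
            per_country_year = 1,
            per_district = d_row$n_districts,
            per_facility = d_row$n_facilities,
            per_population = c_row$adol_pop_2010 *
              (1 + c_row$pop_growth_rate)^(y - 2010) / 1000)
          total <- total + base * mult
        }
      }
    }
  }
  total
}
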