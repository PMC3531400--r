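#' Build coverage scale-up trajectories
#'
#' A trajectory carries a country x intervention pair from its baseline
#' coverage (anchored at the reference year, 2010 by default) linearly up to
#' its target coverage at the end year. In `from_zero` mode the baseline is
#' forced to zero, which is the scenario used to estimate what is currently
#' being spent.
#'
#' With the default 2010 anchor, the first costed year (2011) already
#' carries one fifth of the coverage gap; `anchor_year = 2011` instead holds
#' coverage at baseline in 2011 and closes the gap over the four remaining
#' years.
#'
#' @param country_id,intervention_id Key columns (recycled as needed).
#' @param baseline Baseline coverage fraction(s) at the anchor year.
#' @param target Target coverage fraction(s).
#' @param mode `"incremental"` (scale up from observed baseline) or
#'   `"from_zero"` (baseline forced to 0).
#' @param start_year,end_year Costed window (2011-2015).
#' @param anchor_year Year at which coverage equals the baseline.
#' @return A tibble with one trajectory per row.
#' @export
#' @examples
#' tr <- coverage_trajectory("kenya", "htc", baseline = 0.35, target = 0.95)
#' coverage_at(tr, 2013) # 0.71
coverage_trajectory <- function(country_id, intervention_id, baseline,
                                target, mode = c("incremental", "from_zero"),
                                start_year = 2011, end_year = 2015,
                                anchor_year = 2010) {
  mode <- match.arg(mode)
  if (any(baseline < 0 | baseline > 1) || any(target < 0 | target > 1)) {
    abort_validation("baseline and target coverage must lie in [0, 1]")
  }
  if (!anchor_year %in% c(start_year - 1, start_year)) {
    abort_validation("anchor_year must be start_year or the year before it")
  }
  if (mode == "from_zero") {
    baseline <- 0 * baseline
  }
  tibble(country_id = country_id, intervention_id = intervention_id,
         baseline = baseline, target = target, mode = mode,
         start_year = start_year, end_year = end_year,
         anchor_year = anchor_year)
}

#' Coverage along a linear scale-up trajectory
#'
#' Linear interpolation between the baseline at the anchor year and the
#' target at the end year; at the end year the target is returned exactly.
#'
#' @param traj Trajectory tibble from [coverage_trajectory()].
#' @param year Calendar year(s) within the costed window.
#' @return Coverage fraction(s), vectorized over rows and years.
#' @export
coverage_at <- function(traj, year) {
  if (any(year < traj$start_year | year > traj$end_year)) {
    abort_validation("year outside the trajectory window")
  }
  frac <- (year - traj$anchor_year) / (traj$end_year - traj$anchor_year)
  traj$baseline + frac * (traj$target - traj$baseline)
}

#' Incremental coverage to be costed in a year
#'
#' The scale-up increment above the trajectory's own baseline: the coverage
#' reached in `year` minus the baseline, floored at zero so that countries
#' whose observed coverage already exceeds the target contribute no
#' incremental volume (dis-investment is out of scope). In `from_zero` mode
#' the baseline is zero, so the increment is the full coverage path.
#'
#' @inheritParams coverage_at
#' @return Incremental coverage fraction(s), never negative.
#' @export
#' @examples
#' tr <- coverage_trajectory("kenya", "htc", baseline = 0.35, target = 0.95)
#' incremental_coverage(tr, 2015) # 0.60
incremental_coverage <- function(traj, year) {
  pmax(0, coverage_at(traj, year) - traj$baseline)
}
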