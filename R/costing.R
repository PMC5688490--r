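# Facility-level costing: services = population x need x coverage; per-case
# unit costs from ingredients, provider minutes and OPV/IPD overheads;
# intervention cost = services x unit cost; total = interventions + program.

#' Number of services delivered
#'
#' Services = target population x fraction in need x effective coverage.
#' The need fraction may exceed 1 where a person can require the intervention
#' more than once a year (e.g. diarrhoea treatment). Non-integer counts are
#' retained.
#'
#' @param population persons in the target population.
#' @param need_fraction fraction of the population requiring the intervention
#'   (>= 0, may exceed 1).
#' @param coverage_fraction effective coverage in \[0, 1\].
#' @return number of services (real, vectorized).
#' @examples
#' services_count(1e6, 0.20, 0.50)  # 100000
#' @export
services_count <- function(population, need_fraction, coverage_fraction) {
  if (any(!is.finite(population) | population < 0)) {
    ck_domain_error("population must be finite and >= 0")
  }
  if (any(!is.finite(need_fraction) | need_fraction < 0)) {
    ck_domain_error("need_fraction must be finite and >= 0")
  }
  if (any(!is.finite(coverage_fraction) | coverage_fraction < 0 |
          coverage_fraction > 1)) {
    ck_domain_error("coverage_fraction must lie in [0, 1]")
  }
  population * need_fraction * coverage_fraction
}

#' Cost of one minute of provider time
#'
#' Annual remuneration (wages plus benefits) divided by productive minutes
#' per year: working days x minutes per day x utilization. Utilization is the
#' fraction of paid time spent delivering services, so lower utilization
#' raises the effective cost per delivered minute.
#'
#' @param cadre a single cadre: a list or one-row data.frame with
#'   `annual_remuneration`, `working_days_per_year`, `minutes_per_day`,
#'   `utilization`.
#' @return USD per minute.
#' @examples
#' cost_per_minute(list(annual_remuneration = 12000,
#'                      working_days_per_year = 240,
#'                      minutes_per_day = 480, utilization = 0.5))
#' @export
cost_per_minute <- function(cadre) {
  denom <- cadre$working_days_per_year * cadre$minutes_per_day * cadre$utilization
  if (any(!is.finite(denom) | denom <= 0)) {
    ck_domain_error("working days x minutes per day x utilization must be > 0")
  }
  cadre$annual_remuneration / denom
}

#' Drug and supply cost per case
#'
#' Ingredients approach: for each item, unit price x units per case x the
#' fraction of clients receiving the item, summed over items.
#'
#' @param lines data.frame of ingredient lines (`unit_price`,
#'   `units_per_case`, `pct_receiving`).
#' @return USD per case.
#' @export
drug_supply_cost_per_case <- function(lines) {
  if (nrow(lines) == 0L) return(0)
  sum(lines$unit_price * lines$units_per_case * lines$pct_receiving)
}

#' Labor cost per case
#'
#' Minutes required per case by provider type (minutes per visit x number of
#' visits) costed at each cadre's cost per minute, summed over time lines.
#'
#' @param time_lines data.frame of provider-time lines (`cadre_id`,
#'   `minutes_per_visit`, `n_visits`).
#' @param cadres cadre cost table.
#' @return USD per case.
#' @export
labor_cost_per_case <- function(time_lines, cadres) {
  if (nrow(time_lines) == 0L) return(0)
  idx <- match(time_lines$cadre_id, cadres$cadre_id)
  if (anyNA(idx)) {
    ck_validation_error(sprintf("unknown cadre_id: %s",
                                time_lines$cadre_id[which(is.na(idx))[1L]]),
                        "time_lines")
  }
  cpm <- vapply(idx, function(i) cost_per_minute(cadres[i, ]), numeric(1))
  sum(time_lines$minutes_per_visit * time_lines$n_visits * cpm)
}

#' Other-direct and indirect overhead per case from hotel costs
#'
#' The hotel cost of an outpatient visit (OPV) or inpatient day (IPD) bundles
#' personnel, consumables, other-direct and indirect components. Personnel and
#' consumables are already ingredient-costed, so only the other-direct and
#' indirect proportions of the hotel cost are applied here, which prevents
#' double counting. Health-centre shares apply to OPV costs and hospital
#' shares to IPD costs.
#'
#' @param visit_profile list with `opv_per_case`, `ipd_per_case`.
#' @param hotel_costs list with `cost_per_opv`, `cost_per_ipd` (USD).
#' @param shares_hospital,shares_health_centre [factor_shares()] vectors.
#' @return named numeric `c(other_direct, indirect)` in USD per case.
#' @export
hotel_overhead_per_case <- function(visit_profile, hotel_costs,
                                    shares_hospital, shares_health_centre) {
  opv_usd <- visit_profile$opv_per_case * hotel_costs$cost_per_opv
  ipd_usd <- visit_profile$ipd_per_case * hotel_costs$cost_per_ipd
  c(other_direct = opv_usd * shares_health_centre[["other_direct"]] +
                   ipd_usd * shares_hospital[["other_direct"]],
    indirect     = opv_usd * shares_health_centre[["indirect"]] +
                   ipd_usd * shares_hospital[["indirect"]])
}

#' Per-case unit cost of an intervention
#'
#' Channel-mix-weighted sum of the per-channel drug/supply, labor, and
#' OPV/IPD-overhead costs per case.
#'
#' @param profile an [intervention_profile()].
#' @param db a unit-cost database, see [cost_db()].
#' @return named numeric `c(drugs_supplies, labor, other_direct, indirect)`
#'   in USD per case.
#' @export
unit_cost_per_case <- function(profile, db) {
  out <- c(drugs_supplies = 0, labor = 0, other_direct = 0, indirect = 0)
  for (ch in profile$channels) {
    ho <- hotel_overhead_per_case(ch$visit_profile, db$hotel_costs,
                                  db$shares$hospital, db$shares$health_centre)
    out <- out + ch$mix_fraction *
      c(drugs_supplies = drug_supply_cost_per_case(ch$drug_lines),
        labor = labor_cost_per_case(ch$time_lines, db$cadres),
        ho)
  }
  out
}

#' Annual facility-level cost of one intervention
#'
#' Each component of the per-case unit cost scaled by the number of services,
#' summed over the intervention's need rows (population groups) for the given
#' year. Above-facility costs are zero at the intervention level.
#'
#' @param scn a `costkit_scenario`.
#' @param intervention_id identifier present in the scenario.
#' @param year calendar year within the scenario's year range.
#' @return a [cost_breakdown()] with `above_facility = 0`.
#' @export
intervention_cost <- function(scn, intervention_id, year) {
  profile <- scn$profiles[[intervention_id]]
  if (is.null(profile)) {
    ck_validation_error(sprintf("unknown intervention '%s'", intervention_id),
                        "profiles")
  }
  if (year < scn$year_range[1L] || year > scn$year_range[2L]) {
    ck_validation_error(sprintf("year %d outside scenario range %d-%d", year,
                                scn$year_range[1L], scn$year_range[2L]),
                        "scenario")
  }
  rows <- scn$needs[scn$needs$intervention_id == intervention_id &
                    scn$needs$year == year, , drop = FALSE]
  n_services <- 0
  if (nrow(rows) > 0L) {
    key <- paste(scn$populations$pop_id, scn$populations$year)
    idx <- match(paste(rows$pop_id, rows$year), key)
    if (anyNA(idx)) {
      ck_validation_error(sprintf("no population count for (%s, %d)",
                                  rows$pop_id[which(is.na(idx))[1L]], year),
                          "needs")
    }
    n_services <- sum(services_count(scn$populations$count[idx],
                                     rows$need_fraction,
                                     rows$coverage_fraction))
  }
  u <- unit_cost_per_case(profile, cost_db(scn))
  cost_breakdown(drugs_supplies = n_services * u[["drugs_supplies"]],
                 labor = n_services * u[["labor"]],
                 other_direct = n_services * u[["other_direct"]],
                 indirect = n_services * u[["indirect"]],
                 above_facility = 0)
}

#' Above-facility program costs
#'
#' Fixed-amount categories pass through; markup categories are the markup
#' fraction applied to the total facility-level cost (including drugs).
#'
#' @param spec a [program_cost_spec()].
#' @param facility_total total facility-level cost (USD) the markups apply to.
#' @return list with `categories` (named USD vector) and `total`.
#' @export
program_costs <- function(spec, facility_total) {
  if (!is.finite(facility_total) || facility_total < 0) {
    ck_domain_error("facility_total must be finite and >= 0")
  }
  categories <- vapply(spec, function(e) {
    if (!is.null(e$fixed_amount)) e$fixed_amount
    else e$markup_fraction * facility_total
  }, numeric(1))
  list(categories = categories, total = sum(categories))
}

#' Total annual cost of a scenario
#'
#' Component-wise sum of every intervention's facility-level cost for the
#' year, plus the above-facility program-cost total.
#'
#' @param scn a `costkit_scenario`.
#' @param year calendar year within the scenario's year range.
#' @return a [cost_breakdown()].
#' @export
total_cost <- function(scn, year) {
  ids <- sort(unique(scn$needs$intervention_id))
  acc <- c(drugs_supplies = 0, labor = 0, other_direct = 0, indirect = 0)
  for (id in ids) {
    b <- intervention_cost(scn, id, year)
    acc <- acc + unclass(b)[names(acc)]
  }
  pc <- program_costs(scn$program_costs, sum(acc))
  cost_breakdown(drugs_supplies = acc[["drugs_supplies"]],
                 labor = acc[["labor"]],
                 other_direct = acc[["other_direct"]],
                 indirect = acc[["indirect"]],
                 above_facility = pc$total)
}

#' Per-intervention per-year cost table for a scenario
#'
#' One row per (intervention, year) with the five cost components and the
#' total, plus one `"ALL"` row per year carrying the above-facility program
#' costs and the scenario grand total.
#'
#' @param scn a `costkit_scenario`.
#' @param years years to cost; defaults to the scenario's full range.
#' @return data.frame with columns `intervention_id`, `year`, and the six
#'   breakdown components.
#' @export
cost_summary <- function(scn, years = NULL) {
  if (is.null(years)) years <- scenario_years(scn)
  ids <- sort(unique(scn$needs$intervention_id))
  rows <- list()
  for (yr in years) {
    for (id in ids) {
      b <- intervention_cost(scn, id, yr)
      rows[[length(rows) + 1L]] <- data.frame(
        intervention_id = id, year = yr, as.list(unclass(b)))
    }
    tb <- total_cost(scn, yr)
    rows[[length(rows) + 1L]] <- data.frame(
      intervention_id = "ALL", year = yr, as.list(unclass(tb)))
  }
  do.call(rbind, rows)
}
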