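FACTOR_NAMES <- c("personnel", "consumables", "other_direct", "indirect")

COMPONENT_NAMES <- c("drugs_supplies", "labor", "other_direct", "indirect",
                     "above_facility", "total")

PROGRAM_CATEGORIES <- c("program_management", "research",
                        "monitoring_evaluation", "communication_media_outreach",
                        "training_above_facility", "infrastructure_equipment")

#' Construct a factor-share vector
#'
#' A set of four cost-factor shares (personnel, consumables, other direct
#' costs, indirect costs) for one facility level. Shares are stored as
#' proportions in \[0, 1\]. The four shares are expected to sum to
#' approximately 1; a published table may sum slightly below 1 because of
#' rounding, so sums in \[0.95, 1.01\] are accepted.
#'
#' @param personnel,consumables,other_direct,indirect shares as proportions.
#' @param level facility level the shares apply to, `"hospital"` or
#'   `"health_centre"`.
#' @return a named numeric vector of class `factor_shares` with a `level`
#'   attribute.
#' @seealso [default_factor_shares()]
#' @export
factor_shares <- function(personnel, consumables, other_direct, indirect,
                          level = c("hospital", "health_centre")) {
  level <- match.arg(level)
  s <- c(personnel = unname(personnel), consumables = unname(consumables),
         other_direct = unname(other_direct), indirect = unname(indirect))
  if (any(!is.finite(s) | s < 0 | s > 1)) {
    ck_validation_error("each factor share must lie in [0, 1]", "factor_shares")
  }
  if (sum(s) < 0.95 || sum(s) > 1.01) {
    ck_validation_error(sprintf(
      "factor shares must sum to ~1 (within [0.95, 1.01]); got %.4f", sum(s)),
      "factor_shares")
  }
  structure(s, level = level, class = "factor_shares")
}

#' Packaged default factor shares
#'
#' The default other-direct-cost and indirect-cost proportions applied to
#' outpatient-visit and inpatient-day hotel costs, estimated from a
#' multi-country facility cost dataset via a translog cost function.
#' Hospital shares: personnel 39.0%, consumables 31.7%, other direct 9.8%,
#' indirect 19.5%. Health-centre shares: personnel 36.0%, consumables 23.4%,
#' other direct 8.5%, indirect 29.0% (the published health-centre row sums to
#' 96.9% as printed; it is shipped verbatim unless `renormalize = TRUE`).
#'
#' @param level facility level.
#' @param renormalize if `TRUE`, rescale the row to sum to exactly 1.
#' @return a [factor_shares()] vector.
#' @export
default_factor_shares <- function(level = c("hospital", "health_centre"),
                                  renormalize = FALSE) {
  level <- match.arg(level)
  s <- switch(level,
    hospital      = c(0.390, 0.317, 0.098, 0.195),
    health_centre = c(0.360, 0.234, 0.085, 0.290))
  if (renormalize) s <- s / sum(s)
  factor_shares(s[1L], s[2L], s[3L], s[4L], level = level)
}

#' @export
print.factor_shares <- function(x, ...) {
  cat(sprintf("Factor shares (%s):\n", attr(x, "level")))
  print(round(unclass(x) * 100, 1))
  se <- attr(x, "se")
  if (!is.null(se)) {
    cat("Robust SEs (pct points):\n")
    print(round(se * 100, 2))
  }
  invisible(x)
}

#' Construct a delivery-channel variant of an intervention
#'
#' One delivery channel bundles the per-case treatment inputs: drug/supply
#' ingredient lines, provider-time lines by cadre, and the outpatient-visit /
#' inpatient-day profile, together with the fraction of cases delivered
#' through this channel.
#'
#' @param drug_lines data.frame with columns `item_id`, `unit_price`,
#'   `units_per_case`, `pct_receiving`.
#' @param time_lines data.frame with columns `cadre_id`, `minutes_per_visit`,
#'   `n_visits`.
#' @param opv_per_case,ipd_per_case outpatient visits and inpatient days per
#'   case.
#' @param mix_fraction fraction of cases delivered through this channel.
#' @export
channel <- function(drug_lines = empty_drug_lines(),
                    time_lines = empty_time_lines(),
                    opv_per_case = 0, ipd_per_case = 0, mix_fraction = 1) {
  check_columns(drug_lines, c("item_id", "unit_price", "units_per_case",
                              "pct_receiving"), "drug_lines")
  check_nonneg(drug_lines, c("unit_price", "units_per_case"), "drug_lines")
  check_fraction(drug_lines, "pct_receiving", "drug_lines")
  check_columns(time_lines, c("cadre_id", "minutes_per_visit", "n_visits"),
                "time_lines")
  check_nonneg(time_lines, c("minutes_per_visit", "n_visits"), "time_lines")
  if (!is.finite(opv_per_case) || opv_per_case < 0 ||
      !is.finite(ipd_per_case) || ipd_per_case < 0) {
    ck_validation_error("opv_per_case and ipd_per_case must be >= 0", "visits")
  }
  if (!is.finite(mix_fraction) || mix_fraction < 0 || mix_fraction > 1) {
    ck_validation_error("mix_fraction must lie in [0, 1]", "channel_mix")
  }
  structure(list(drug_lines = drug_lines, time_lines = time_lines,
                 visit_profile = list(opv_per_case = opv_per_case,
                                      ipd_per_case = ipd_per_case),
                 mix_fraction = mix_fraction),
            class = "costkit_channel")
}

empty_drug_lines <- function() {
  data.frame(item_id = character(), unit_price = numeric(),
             units_per_case = numeric(), pct_receiving = numeric())
}

empty_time_lines <- function() {
  data.frame(cadre_id = character(), minutes_per_visit = numeric(),
             n_visits = numeric())
}

#' Construct an intervention profile
#'
#' The per-case treatment-input profile for one intervention, as one or more
#' named delivery channels whose mix fractions must sum to 1.
#'
#' @param intervention_id identifier.
#' @param channels named list of [channel()] objects.
#' @export
intervention_profile <- function(intervention_id, channels) {
  if (length(channels) < 1L) {
    ck_validation_error(sprintf("intervention '%s' has no channels",
                                intervention_id), "profiles")
  }
  mix <- vapply(channels, function(ch) ch$mix_fraction, numeric(1))
  if (abs(sum(mix) - 1) > 1e-9) {
    ck_validation_error(sprintf(
      "channel mix fractions for intervention '%s' sum to %.6f, not 1",
      intervention_id, sum(mix)), "channel_mix")
  }
  structure(list(intervention_id = intervention_id, channels = channels),
            class = "costkit_profile")
}

#' Construct an above-facility program-cost specification
#'
#' Each of the six above-facility categories (program management, research,
#' monitoring & evaluation, communication/media/outreach, above-facility
#' training, infrastructure & equipment) is specified either as a fixed annual
#' amount in USD or as a markup fraction applied to the total facility-level
#' cost.
#'
#' @param ... named category entries, each a list with exactly one of
#'   `fixed_amount` or `markup_fraction`. Unspecified categories default to a
#'   fixed amount of 0.
#' @export
program_cost_spec <- function(...) {
  entries <- list(...)
  bad <- setdiff(names(entries), PROGRAM_CATEGORIES)
  if (length(bad) > 0L) {
    ck_validation_error(sprintf("unknown program-cost category: %s",
                                paste(bad, collapse = ", ")), "program_costs")
  }
  spec <- stats::setNames(
    rep(list(list(fixed_amount = 0)), length(PROGRAM_CATEGORIES)),
    PROGRAM_CATEGORIES)
  for (nm in names(entries)) {
    e <- entries[[nm]]
    keys <- intersect(names(e), c("fixed_amount", "markup_fraction"))
    if (length(keys) != 1L) {
      ck_validation_error(sprintf(
        "category '%s' must have exactly one of fixed_amount, markup_fraction",
        nm), "program_costs")
    }
    v <- e[[keys]]
    if (!is.finite(v) || v < 0) {
      ck_validation_error(sprintf("category '%s': %s must be >= 0", nm, keys),
                          "program_costs")
    }
    spec[[nm]] <- e[keys]
  }
  structure(spec, class = "costkit_program_spec")
}

#' Construct a cost breakdown
#'
#' The disaggregated annual cost of an intervention or scenario: drug and
#' supply costs, labor costs, other direct costs (reported in exports as
#' "other recurrent costs"), indirect costs (reported as "capital costs"),
#' and above-facility program costs. `total` is always the exact sum of the
#' five components.
#'
#' @param drugs_supplies,labor,other_direct,indirect,above_facility USD.
#' @return named numeric vector of class `cost_breakdown` (6 elements, the
#'   last being `total`).
#' @export
cost_breakdown <- function(drugs_supplies = 0, labor = 0, other_direct = 0,
                           indirect = 0, above_facility = 0) {
  x <- c(drugs_supplies = drugs_supplies, labor = labor,
         other_direct = other_direct, indirect = indirect,
         above_facility = above_facility)
  if (any(!is.finite(x) | x < 0)) {
    ck_validation_error("cost components must be finite and >= 0",
                        "cost_breakdown")
  }
  structure(c(x, total = sum(x)), class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("Cost breakdown (USD):\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Assemble and validate a costing scenario
#'
#' A scenario bundles everything needed to cost an intervention package over a
#' range of years: target populations, need and effective-coverage fractions,
#' intervention treatment-input profiles, cadre remuneration, hotel costs per
#' outpatient visit / inpatient day, factor shares for both facility levels,
#' and the above-facility program-cost specification. Cross-references
#' (intervention to profile, cadre to cost, need row to population) are
#' validated at construction.
#'
#' @param name scenario name.
#' @param year_range integer vector `c(start, end)`, inclusive.
#' @param populations data.frame `pop_id, year, count`.
#' @param needs data.frame `intervention_id, pop_id, year, need_fraction,
#'   coverage_fraction`. `need_fraction` may exceed 1 (more than one case per
#'   person-year); `coverage_fraction` is the effective coverage in \[0, 1\].
#' @param profiles named list of [intervention_profile()] objects.
#' @param cadres data.frame `cadre_id, annual_remuneration,
#'   working_days_per_year, minutes_per_day, utilization`.
#' @param hotel_costs list with `cost_per_opv`, `cost_per_ipd` (USD).
#' @param shares list with elements `hospital` and `health_centre`, each a
#'   [factor_shares()] vector.
#' @param program_costs a [program_cost_spec()].
#' @return validated object of class `costkit_scenario`.
#' @export
scenario <- function(name, year_range, populations, needs, profiles, cadres,
                     hotel_costs, shares = list(
                       hospital = default_factor_shares("hospital"),
                       health_centre = default_factor_shares("health_centre")),
                     program_costs = program_cost_spec()) {
  year_range <- as.integer(year_range)
  if (length(year_range) != 2L || year_range[2L] < year_range[1L]) {
    ck_validation_error("year_range must be c(start, end) with end >= start",
                        "scenario")
  }

  check_columns(populations, c("pop_id", "year", "count"), "populations")
  check_nonneg(populations, "count", "populations")
  dup <- duplicated(populations[c("pop_id", "year")])
  if (any(dup)) {
    ck_validation_error("duplicate (pop_id, year)", "populations", which(dup)[1L])
  }

  check_columns(needs, c("intervention_id", "pop_id", "year", "need_fraction",
                         "coverage_fraction"), "needs")
  check_nonneg(needs, "need_fraction", "needs")
  check_fraction(needs, "coverage_fraction", "needs")

  check_columns(cadres, c("cadre_id", "annual_remuneration",
                          "working_days_per_year", "minutes_per_day",
                          "utilization"), "cadres")
  check_nonneg(cadres, "annual_remuneration", "cadres")
  bad <- which(cadres$working_days_per_year <= 0 | cadres$minutes_per_day <= 0 |
               cadres$utilization <= 0 | cadres$utilization > 1)
  if (length(bad) > 0L) {
    ck_validation_error(
      "working_days_per_year and minutes_per_day must be > 0; utilization in (0, 1]",
      "cadres", bad[1L])
  }

  if (!is.finite(hotel_costs$cost_per_opv) || hotel_costs$cost_per_opv < 0 ||
      !is.finite(hotel_costs$cost_per_ipd) || hotel_costs$cost_per_ipd < 0) {
    ck_validation_error("hotel costs must be >= 0", "hotel_costs")
  }

  for (lv in c("hospital", "health_centre")) {
    if (!inherits(shares[[lv]], "factor_shares")) {
      ck_validation_error(sprintf("shares$%s must be a factor_shares vector", lv),
                          "shares")
    }
  }
  if (!inherits(program_costs, "costkit_program_spec")) {
    program_costs <- do.call(program_cost_spec, program_costs)
  }

  # cross-references
  unknown <- setdiff(unique(needs$intervention_id), names(profiles))
  if (length(unknown) > 0L) {
    ck_validation_error(sprintf("needs reference unknown intervention(s): %s",
                                paste(unknown, collapse = ", ")), "needs")
  }
  unknown <- setdiff(unique(needs$pop_id), unique(populations$pop_id))
  if (length(unknown) > 0L) {
    ck_validation_error(sprintf("needs reference unknown population(s): %s",
                                paste(unknown, collapse = ", ")), "needs")
  }
  used_cadres <- unique(unlist(lapply(profiles, function(p)
    lapply(p$channels, function(ch) ch$time_lines$cadre_id))))
  unknown <- setdiff(used_cadres, cadres$cadre_id)
  if (length(unknown) > 0L) {
    ck_validation_error(sprintf("time lines reference unknown cadre(s): %s",
                                paste(unknown, collapse = ", ")), "time_lines")
  }

  structure(list(name = name, year_range = year_range,
                 populations = populations, needs = needs, profiles = profiles,
                 cadres = cadres, hotel_costs = hotel_costs, shares = shares,
                 program_costs = program_costs),
            class = "costkit_scenario")
}

#' @export
print.costkit_scenario <- function(x, ...) {
  cat(sprintf("Costing scenario '%s': %d interventions, %d cadres, years %d-%d\n",
              x$name, length(x$profiles), nrow(x$cadres),
              x$year_range[1L], x$year_range[2L]))
  invisible(x)
}

#' Extract the unit-cost database of a scenario
#'
#' The components of a scenario consumed by the per-case costing operations:
#' cadre costs, hotel costs, and the factor-share pair.
#'
#' @param scn a `costkit_scenario`.
#' @export
cost_db <- function(scn) {
  list(cadres = scn$cadres, hotel_costs = scn$hotel_costs, shares = scn$shares)
}

#' Years covered by a scenario
#' @param scn a `costkit_scenario`.
#' @export
scenario_years <- function(scn) {
  seq.int(scn$year_range[1L], scn$year_range[2L])
}
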