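# Scenario comparison and cost-effectiveness summaries. Incremental costs
# come from re-running the costing engine on both scenarios; lives saved are
# an external input (the mortality-impact engine is deliberately decoupled).

#' Compare the cost streams of two scenarios
#'
#' Computes baseline, alternative and incremental (alternative minus
#' baseline) cost breakdowns per intervention-year, plus grand totals per
#' year. The two scenarios must cover identical year ranges and intervention
#' sets; incremental components may be negative.
#'
#' @param baseline,alternative `costkit_scenario` objects.
#' @return object of class `scenario_comparison`: a list with
#'   `by_intervention` (long data.frame: `intervention_id, year, component,
#'   baseline, alternative, incremental`), `totals` (same per year, across
#'   interventions including above-facility costs), and the scenario names.
#' @export
compare_scenarios <- function(baseline, alternative) {
  if (!identical(as.integer(baseline$year_range),
                 as.integer(alternative$year_range))) {
    ck_validation_error("scenarios cover different year ranges", "compare")
  }
  ids_b <- sort(unique(baseline$needs$intervention_id))
  ids_a <- sort(unique(alternative$needs$intervention_id))
  if (!identical(ids_b, ids_a)) {
    ck_validation_error("scenarios cover different intervention sets",
                        "compare")
  }
  years <- scenario_years(baseline)
  rows <- list()
  tot <- list()
  for (yr in years) {
    for (id in ids_b) {
      b <- unclass(intervention_cost(baseline, id, yr))
      a <- unclass(intervention_cost(alternative, id, yr))
      rows[[length(rows) + 1L]] <- data.frame(
        intervention_id = id, year = yr, component = COMPONENT_NAMES,
        baseline = b[COMPONENT_NAMES], alternative = a[COMPONENT_NAMES],
        incremental = a[COMPONENT_NAMES] - b[COMPONENT_NAMES])
    }
    b <- unclass(total_cost(baseline, yr))
    a <- unclass(total_cost(alternative, yr))
    tot[[length(tot) + 1L]] <- data.frame(
      year = yr, component = COMPONENT_NAMES,
      baseline = b[COMPONENT_NAMES], alternative = a[COMPONENT_NAMES],
      incremental = a[COMPONENT_NAMES] - b[COMPONENT_NAMES])
  }
  by_intervention <- do.call(rbind, rows)
  totals <- do.call(rbind, tot)
  rownames(by_intervention) <- rownames(totals) <- NULL
  structure(list(baseline_name = baseline$name,
                 alternative_name = alternative$name,
                 by_intervention = by_intervention, totals = totals),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  inc <- sum(x$totals$incremental[x$totals$component == "total"])
  cat(sprintf("Scenario comparison: '%s' vs baseline '%s'\n",
              x$alternative_name, x$baseline_name))
  cat(sprintf("Incremental total cost over %d year(s): %s USD\n",
              length(unique(x$totals$year)),
              format(round(inc), big.mark = ",")))
  invisible(x)
}

#' Incremental cost per life saved
#'
#' @param incremental_cost USD (may be negative for cost-saving changes).
#' @param incremental_lives_saved lives saved (must be nonzero).
#' @return USD per life saved; sign preserved.
#' @export
cost_per_life_saved <- function(incremental_cost, incremental_lives_saved) {
  if (any(incremental_lives_saved == 0)) {
    ck_domain_error("cost per life saved is undefined when incremental lives saved is 0")
  }
  incremental_cost / incremental_lives_saved
}

#' Cost-effectiveness league table
#'
#' Ranks interventions by incremental cost per life saved, ascending.
#' Incremental costs are the comparison's per-intervention totals summed over
#' years; incremental lives saved per intervention are supplied externally.
#' Dominated entries (non-positive lives saved with positive incremental
#' cost) are flagged and listed last rather than dropped; ties are broken by
#' `intervention_id`.
#'
#' @param comparison a [compare_scenarios()] result.
#' @param impacts data.frame with `intervention_id` and `lives_saved`
#'   (incremental lives saved of the alternative over the baseline; a `year`
#'   column, if present, is summed over). Every compared intervention needs a
#'   row.
#' @return data.frame `intervention_id, incremental_cost, lives_saved,
#'   cost_per_life_saved, dominated`, ranked.
#' @export
league_table <- function(comparison, impacts) {
  check_columns(impacts, c("intervention_id", "lives_saved"), "impacts")
  bi <- comparison$by_intervention
  inc <- stats::aggregate(incremental ~ intervention_id,
                          data = bi[bi$component == "total", , drop = FALSE],
                          FUN = sum)
  lives <- stats::aggregate(lives_saved ~ intervention_id, data = impacts,
                            FUN = sum)
  missing <- setdiff(inc$intervention_id, lives$intervention_id)
  if (length(missing) > 0L) {
    ck_validation_error(sprintf("missing impact row for intervention(s): %s",
                                paste(missing, collapse = ", ")), "impacts")
  }
  m <- merge(inc, lives, by = "intervention_id")
  ratio <- ifelse(m$lives_saved == 0, Inf,
                  m$incremental / m$lives_saved)
  dominated <- m$lives_saved <= 0 & m$incremental > 0
  out <- data.frame(intervention_id = m$intervention_id,
                    incremental_cost = m$incremental,
                    lives_saved = m$lives_saved,
                    cost_per_life_saved = ifelse(m$lives_saved == 0,
                                                 NA_real_, ratio),
                    dominated = dominated)
  ord <- order(dominated, ifelse(dominated, 0, ratio), out$intervention_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a scenario comparison to CSV
#'
#' @param comparison a [compare_scenarios()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  bi <- comparison$by_intervention
  tot <- comparison$totals
  tot$intervention_id <- "ALL"
  out <- rbind(bi, tot[names(bi)])
  for (nm in c("baseline", "alternative", "incremental")) {
    out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
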