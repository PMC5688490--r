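# CSV/JSON readers and writers. All tables are UTF-8, header row, '.' decimal.
# Doubles are written with 17 significant digits so that load(write(x))
# round-trips bit-exactly.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  # trim to the shortest representation that still round-trips
  for (d in 1:16) {
    cand <- sprintf("%.*g", d, x)
    ok <- as.numeric(cand) == x
    out[ok] <- cand[ok]
  }
  out
}

write_csv_ck <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_csv_ck <- function(path, table, comment = "") {
  if (!file.exists(path)) {
    ck_validation_error(sprintf("missing file: %s", path), table)
  }
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = comment,
                  fileEncoding = "UTF-8")
}

as_num_cols <- function(df, cols) {
  for (nm in cols) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Load a scenario from a scenario.json file and its CSV tables
#'
#' `scenario.json` holds the scenario name, year range, pointers to the CSV
#' tables (relative to its own directory), the channel mix per intervention,
#' and the program-cost specification. All tables are validated and
#' cross-referenced; malformed rows raise a typed validation error naming the
#' offending table and row.
#'
#' @param path path to `scenario.json`, or to a directory containing one.
#' @param percent if `TRUE`, the fraction columns (`need_fraction`,
#'   `coverage_fraction`, `pct_receiving`, and the share columns) are given in
#'   percent in the CSVs and are divided by 100 on load.
#' @return a validated `costkit_scenario`.
#' @seealso [write_scenario()], [generate_country_fixture()]
#' @export
load_scenario <- function(path, percent = FALSE) {
  if (dir.exists(path)) path <- file.path(path, "scenario.json")
  if (!file.exists(path)) {
    ck_validation_error(sprintf("missing file: %s", path), "scenario.json")
  }
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  fp <- function(key) {
    f <- meta$files[[key]]
    if (is.null(f)) ck_validation_error(
      sprintf("scenario.json lists no '%s' file", key), "scenario.json")
    file.path(base, f)
  }
  pct <- function(x) if (percent) x / 100 else x

  populations <- read_csv_ck(fp("populations"), "populations")
  check_columns(populations, c("pop_id", "year", "count"), "populations")
  populations <- as_num_cols(populations, "count")
  populations$year <- as.integer(populations$year)

  needs <- read_csv_ck(fp("needs"), "needs")
  check_columns(needs, c("intervention_id", "pop_id", "year", "need_fraction",
                         "coverage_fraction"), "needs")
  needs <- as_num_cols(needs, c("need_fraction", "coverage_fraction"))
  needs$year <- as.integer(needs$year)
  needs$need_fraction <- pct(needs$need_fraction)
  needs$coverage_fraction <- pct(needs$coverage_fraction)

  drug_lines <- read_csv_ck(fp("drug_lines"), "drug_lines")
  check_columns(drug_lines, c("intervention_id", "channel", "item_id",
                              "unit_price", "units_per_case", "pct_receiving"),
                "drug_lines")
  drug_lines <- as_num_cols(drug_lines,
                            c("unit_price", "units_per_case", "pct_receiving"))
  drug_lines$pct_receiving <- pct(drug_lines$pct_receiving)

  time_lines <- read_csv_ck(fp("time_lines"), "time_lines")
  check_columns(time_lines, c("intervention_id", "channel", "cadre_id",
                              "minutes_per_visit", "n_visits"), "time_lines")
  time_lines <- as_num_cols(time_lines, c("minutes_per_visit", "n_visits"))

  visits <- read_csv_ck(fp("visits"), "visits")
  check_columns(visits, c("intervention_id", "channel", "opv_per_case",
                          "ipd_per_case"), "visits")
  visits <- as_num_cols(visits, c("opv_per_case", "ipd_per_case"))

  cadres <- read_csv_ck(fp("cadres"), "cadres")
  check_columns(cadres, c("cadre_id", "annual_remuneration",
                          "working_days_per_year", "minutes_per_day",
                          "utilization"), "cadres")
  cadres <- as_num_cols(cadres, c("annual_remuneration", "working_days_per_year",
                                  "minutes_per_day", "utilization"))

  hotel <- read_csv_ck(fp("hotel_costs"), "hotel_costs")
  check_columns(hotel, c("cost_per_opv", "cost_per_ipd"), "hotel_costs")
  hotel_costs <- list(cost_per_opv = as.numeric(hotel$cost_per_opv[1L]),
                      cost_per_ipd = as.numeric(hotel$cost_per_ipd[1L]))

  shares_df <- read_csv_ck(fp("shares"), "shares")
  check_columns(shares_df, c("level", FACTOR_NAMES), "shares")
  shares <- list()
  for (i in seq_len(nrow(shares_df))) {
    lv <- shares_df$level[i]
    shares[[lv]] <- factor_shares(pct(shares_df$personnel[i]),
                                  pct(shares_df$consumables[i]),
                                  pct(shares_df$other_direct[i]),
                                  pct(shares_df$indirect[i]), level = lv)
  }

  # channel list: authoritative order from scenario.json's channel_mix when
  # present, otherwise the channels found in the treatment-input tables
  mix <- meta$channel_mix
  if (is.null(mix) || NROW(mix) == 0L) {
    found <- unique(rbind(drug_lines[c("intervention_id", "channel")],
                          time_lines[c("intervention_id", "channel")],
                          visits[c("intervention_id", "channel")]))
    found$mix_fraction <- 1
    mix <- found
  }
  mix <- as.data.frame(mix, stringsAsFactors = FALSE)
  profiles <- list()
  for (id in unique(mix$intervention_id)) {
    m <- mix[mix$intervention_id == id, , drop = FALSE]
    chans <- list()
    for (i in seq_len(nrow(m))) {
      chn <- m$channel[i]
      dl <- drug_lines[drug_lines$intervention_id == id &
                       drug_lines$channel == chn,
                       c("item_id", "unit_price", "units_per_case",
                         "pct_receiving"), drop = FALSE]
      tl <- time_lines[time_lines$intervention_id == id &
                       time_lines$channel == chn,
                       c("cadre_id", "minutes_per_visit", "n_visits"),
                       drop = FALSE]
      vs <- visits[visits$intervention_id == id & visits$channel == chn, ,
                   drop = FALSE]
      opv <- if (nrow(vs) > 0L) vs$opv_per_case[1L] else 0
      ipd <- if (nrow(vs) > 0L) vs$ipd_per_case[1L] else 0
      rownames(dl) <- NULL
      rownames(tl) <- NULL
      chans[[chn]] <- channel(drug_lines = dl, time_lines = tl,
                              opv_per_case = opv, ipd_per_case = ipd,
                              mix_fraction = as.numeric(m$mix_fraction[i]))
    }
    profiles[[id]] <- intervention_profile(id, chans)
  }

  pc <- meta$program_costs
  program <- if (is.null(pc)) program_cost_spec() else
    do.call(program_cost_spec, lapply(pc, as.list))

  scenario(name = meta$name, year_range = unlist(meta$year_range),
           populations = populations, needs = needs, profiles = profiles,
           cadres = cadres, hotel_costs = hotel_costs, shares = shares,
           program_costs = program)
}

#' Write a scenario to a directory as scenario.json plus CSV tables
#'
#' Inverse of [load_scenario()]: `load_scenario(write_scenario(scn, dir))`
#' reproduces the scenario field-for-field.
#'
#' @param scn a `costkit_scenario`.
#' @param dir output directory (created if needed).
#' @return the path to the written `scenario.json`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_ck(scn$populations, file.path(dir, "populations.csv"))
  write_csv_ck(scn$needs, file.path(dir, "needs.csv"))
  write_csv_ck(scn$cadres, file.path(dir, "cadres.csv"))
  write_csv_ck(data.frame(cost_per_opv = scn$hotel_costs$cost_per_opv,
                          cost_per_ipd = scn$hotel_costs$cost_per_ipd),
               file.path(dir, "hotel_costs.csv"))
  shares_df <- do.call(rbind, lapply(names(scn$shares), function(lv) {
    s <- scn$shares[[lv]]
    data.frame(level = lv, personnel = s[["personnel"]],
               consumables = s[["consumables"]],
               other_direct = s[["other_direct"]], indirect = s[["indirect"]])
  }))
  write_csv_ck(shares_df, file.path(dir, "shares.csv"))

  dl <- list(); tl <- list(); vs <- list(); mix <- list()
  for (p in scn$profiles) {
    for (chn in names(p$channels)) {
      ch <- p$channels[[chn]]
      if (nrow(ch$drug_lines) > 0L) {
        dl[[length(dl) + 1L]] <- cbind(
          data.frame(intervention_id = p$intervention_id, channel = chn),
          ch$drug_lines)
      }
      if (nrow(ch$time_lines) > 0L) {
        tl[[length(tl) + 1L]] <- cbind(
          data.frame(intervention_id = p$intervention_id, channel = chn),
          ch$time_lines)
      }
      vs[[length(vs) + 1L]] <- data.frame(
        intervention_id = p$intervention_id, channel = chn,
        opv_per_case = ch$visit_profile$opv_per_case,
        ipd_per_case = ch$visit_profile$ipd_per_case)
      mix[[length(mix) + 1L]] <- data.frame(
        intervention_id = p$intervention_id, channel = chn,
        mix_fraction = ch$mix_fraction)
    }
  }
  bind_or_empty <- function(lst, proto) {
    if (length(lst) > 0L) do.call(rbind, lst) else proto
  }
  write_csv_ck(bind_or_empty(dl, cbind(
    data.frame(intervention_id = character(), channel = character()),
    empty_drug_lines())), file.path(dir, "drug_lines.csv"))
  write_csv_ck(bind_or_empty(tl, cbind(
    data.frame(intervention_id = character(), channel = character()),
    empty_time_lines())), file.path(dir, "time_lines.csv"))
  write_csv_ck(do.call(rbind, vs), file.path(dir, "visits.csv"))

  meta <- list(
    name = scn$name,
    year_range = scn$year_range,
    files = list(populations = "populations.csv", needs = "needs.csv",
                 drug_lines = "drug_lines.csv", time_lines = "time_lines.csv",
                 visits = "visits.csv", cadres = "cadres.csv",
                 hotel_costs = "hotel_costs.csv", shares = "shares.csv"),
    channel_mix = do.call(rbind, mix),
    program_costs = unclass(scn$program_costs))
  path <- file.path(dir, "scenario.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a per-intervention per-year cost table to CSV
#'
#' The wide table (one [cost_breakdown()] per row, as produced by
#' [cost_summary()]) is written in tidy long form: one row per
#' (intervention, year, component), components including the total. A header
#' comment notes the report-label mapping: `other_direct` is reported as
#' "other recurrent costs" and `indirect` as "capital costs".
#'
#' @param results data.frame with `intervention_id`, `year`, and the six
#'   breakdown component columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (NROW(results) == 0L) {
    ck_validation_error("results table is empty", "results")
  }
  check_columns(results, c("intervention_id", "year", COMPONENT_NAMES),
                "results")
  long <- do.call(rbind, lapply(COMPONENT_NAMES, function(comp) {
    data.frame(intervention_id = results$intervention_id,
               year = results$year, component = comp, usd = results[[comp]])
  }))
  ord <- order(match(long$intervention_id, unique(results$intervention_id)),
               long$year, match(long$component, COMPONENT_NAMES))
  long <- long[ord, , drop = FALSE]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "# costkit cost results (USD, constant prices)",
    "# report labels: other_direct = 'other recurrent costs'; indirect = 'capital costs'"),
    con)
  utils::write.table(
    data.frame(intervention_id = long$intervention_id, year = long$year,
               component = long$component, usd = fmt_num(long$usd)),
    con, sep = ",", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a results CSV written by [write_results()]
#' @param path CSV path.
#' @return long data.frame `intervention_id, year, component, usd`.
#' @export
read_results <- function(path) {
  df <- read_csv_ck(path, "results", comment = "#")
  check_columns(df, c("intervention_id", "year", "component", "usd"), "results")
  df$usd <- as.numeric(df$usd)
  df$year <- as.integer(df$year)
  df
}

#' Read a facility-level cost table
#'
#' One row per facility: level (`hospital` or `health_centre`), total annual
#' cost, the four factor prices (all strictly positive) and output volume.
#' Optional `exp_*` columns carry per-factor expenditures, used only by the
#' share-system estimator.
#'
#' @param path CSV path.
#' @return validated data.frame of facility cost records.
#' @export
read_facilities <- function(path) {
  df <- read_csv_ck(path, "facilities")
  validate_facilities(df)
}

validate_facilities <- function(df) {
  price_cols <- paste0("price_", FACTOR_NAMES)
  check_columns(df, c("facility_id", "level", "total_cost", price_cols,
                      "output_volume"), "facilities")
  df <- as_num_cols(df, c("total_cost", price_cols, "output_volume"))
  bad <- which(df$total_cost <= 0 | df$output_volume <= 0 |
               apply(as.matrix(df[price_cols]) <= 0, 1L, any))
  if (length(bad) > 0L) {
    ck_validation_error("total_cost, prices and output_volume must be > 0",
                        "facilities", bad[1L])
  }
  unknown <- setdiff(unique(df$level), c("hospital", "health_centre"))
  if (length(unknown) > 0L) {
    ck_validation_error(sprintf("unknown facility level: %s",
                                paste(unknown, collapse = ", ")), "facilities")
  }
  df
}

#' Read an impacts table (lives saved per scenario-year)
#'
#' @param path CSV path with columns `scenario, year, lives_saved` and
#'   optionally `intervention_id` (required for intervention-level league
#'   tables).
#' @return data.frame.
#' @export
read_impacts <- function(path) {
  df <- read_csv_ck(path, "impacts")
  check_columns(df, c("scenario", "year", "lives_saved"), "impacts")
  df$lives_saved <- as.numeric(df$lives_saved)
  df$year <- as.integer(df$year)
  df
}

#' Linearly interpolate interior years of an annual table
#'
#' Populations and coverage must normally be supplied for every year of a
#' scenario; this helper fills interior years by linear interpolation within
#' each group, given values at (at least) the endpoint years.
#'
#' @param df annual table with a `year` column.
#' @param years full set of years to fill.
#' @param by_cols grouping columns (e.g. `"pop_id"`).
#' @param value_cols numeric columns to interpolate.
#' @return data.frame covering every (group, year) combination.
#' @export
interpolate_years <- function(df, years, by_cols, value_cols) {
  key <- interaction(df[by_cols], drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    if (nrow(g) < 2L) {
      ck_validation_error("interpolation needs at least two years per group",
                          "interpolate")
    }
    res <- g[rep(1L, length(years)), , drop = FALSE]
    res$year <- as.integer(years)
    for (v in value_cols) {
      res[[v]] <- stats::approx(g$year, g[[v]], xout = years, rule = 2)$y
    }
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
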