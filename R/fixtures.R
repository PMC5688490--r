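# Synthetic data generators: a toy-country scenario (populations, needs,
# treatment-input profiles, cadre costs, hotel costs, program costs) and a
# facility-level cost dataset drawn from a known translog data-generating
# process. Both are deterministic under the config seed.

#' Configuration for the synthetic-data generators
#'
#' @param seed integer RNG seed; identical seeds give byte-identical outputs.
#' @param n_interventions number of interventions in the toy country.
#' @param n_cadres number of provider cadres.
#' @param year_range inclusive calendar-year range.
#' @param n_facilities named integer vector: facilities to simulate per level.
#' @param true_shares named list (`hospital`, `health_centre`) of length-4
#'   share vectors summing to 1; defaults echo the packaged default shares
#'   (the health-centre row renormalized to sum to 1).
#' @param noise_sd standard deviation of the multiplicative lognormal cost
#'   noise (log scale).
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 42L, n_interventions = 10L, n_cadres = 3L,
                           year_range = c(2026L, 2030L),
                           n_facilities = c(hospital = 300L,
                                            health_centre = 300L),
                           true_shares = list(
                             hospital = c(0.390, 0.317, 0.098, 0.195),
                             health_centre = c(0.360, 0.234, 0.085, 0.290) /
                                             0.969),
                           noise_sd = 0.05) {
  if (n_interventions < 1L || n_cadres < 1L) {
    ck_validation_error("n_interventions and n_cadres must be >= 1", "config")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    ck_validation_error("noise_sd must be >= 0", "config")
  }
  for (lv in names(true_shares)) {
    s <- true_shares[[lv]]
    if (length(s) != 4L || any(s <= 0) || abs(sum(s) - 1) > 1e-8) {
      ck_validation_error(sprintf(
        "true_shares$%s must be 4 positive values summing to 1", lv), "config")
    }
  }
  structure(list(seed = as.integer(seed), n_interventions = n_interventions,
                 n_cadres = n_cadres, year_range = as.integer(year_range),
                 n_facilities = n_facilities, true_shares = true_shares,
                 noise_sd = noise_sd),
            class = "fixture_config")
}

CADRE_POOL <- c("nurse", "midwife", "physician", "chw", "lab_tech",
                "pharmacist", "clinical_officer", "aide")

#' Generate a synthetic toy-country scenario
#'
#' Builds a complete, validatable scenario: target populations with mild
#' growth, need and coverage trajectories (coverage ramping up over the year
#' range), intervention profiles with one or two delivery channels and 1-4
#' drug/supply lines each, cadre costs, hotel costs, the packaged default
#' factor shares, and a nonzero program-cost specification. Deterministic
#' under `config$seed`.
#'
#' @param config a [fixture_config()].
#' @param dir optional directory; when given, the scenario is also written
#'   out via [write_scenario()].
#' @return the `costkit_scenario` (invisibly when `dir` is given).
#' @export
generate_country_fixture <- function(config = fixture_config(), dir = NULL) {
  set.seed(config$seed)
  years <- seq.int(config$year_range[1L], config$year_range[2L])
  n_years <- length(years)

  pops <- c("pregnant_women", "births", "children_u5")
  base_count <- c(pregnant_women = 400000, births = 380000,
                  children_u5 = 1800000)
  growth <- stats::runif(length(pops), 0.01, 0.03)
  populations <- do.call(rbind, lapply(seq_along(pops), function(i) {
    data.frame(pop_id = pops[i], year = years,
               count = round(base_count[[i]] *
                             (1 + growth[i])^(seq_len(n_years) - 1)))
  }))
  rownames(populations) <- NULL

  cadre_ids <- CADRE_POOL[seq_len(min(config$n_cadres, length(CADRE_POOL)))]
  cadres <- data.frame(
    cadre_id = cadre_ids,
    annual_remuneration = round(stats::runif(length(cadre_ids), 3000, 24000)),
    working_days_per_year = 230,
    minutes_per_day = 480,
    utilization = round(stats::runif(length(cadre_ids), 0.5, 0.9), 2))

  ids <- sprintf("intv_%02d", seq_len(config$n_interventions))
  profiles <- list()
  needs <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    n_chan <- sample(1:2, 1L)
    chan_names <- c("facility", "outreach")[seq_len(n_chan)]
    mix <- if (n_chan == 1L) 1 else {
      m <- round(stats::runif(1, 0.3, 0.7), 2)
      c(m, 1 - m)
    }
    chans <- list()
    for (ci in seq_len(n_chan)) {
      n_drugs <- sample(1:4, 1L)
      dl <- data.frame(
        item_id = sprintf("%s_item_%d", id, seq_len(n_drugs)),
        unit_price = round(stats::runif(n_drugs, 0.05, 5), 4),
        units_per_case = sample(1:10, n_drugs, replace = TRUE),
        pct_receiving = round(stats::runif(n_drugs, 0.5, 1), 2))
      n_time <- sample(1:2, 1L)
      tl <- data.frame(
        cadre_id = sample(cadre_ids, n_time),
        minutes_per_visit = round(stats::runif(n_time, 5, 30), 1),
        n_visits = sample(1:4, n_time, replace = TRUE))
      opv <- round(stats::runif(1, 0.5, 4), 1)
      ipd <- if (stats::runif(1) < 0.3) round(stats::runif(1, 0.5, 3), 1) else 0
      chans[[chan_names[ci]]] <- channel(
        drug_lines = dl, time_lines = tl,
        opv_per_case = opv, ipd_per_case = ipd, mix_fraction = mix[ci])
    }
    profiles[[id]] <- intervention_profile(id, chans)

    pop <- pops[1L + (i - 1L) %% length(pops)]
    need <- round(stats::runif(1, 0.05, 1.2), 3)
    cov0 <- stats::runif(1, 0.2, 0.5)
    cov1 <- stats::runif(1, 0.6, 0.95)
    cov <- round(seq(cov0, cov1, length.out = n_years), 3)
    needs[[id]] <- data.frame(intervention_id = id, pop_id = pop, year = years,
                              need_fraction = need, coverage_fraction = cov)
  }
  needs <- do.call(rbind, needs)
  rownames(needs) <- NULL

  hotel_costs <- list(cost_per_opv = round(stats::runif(1, 1, 5), 2),
                      cost_per_ipd = round(stats::runif(1, 5, 20), 2))

  scn <- scenario(
    name = sprintf("toy-country-seed%d", config$seed),
    year_range = config$year_range,
    populations = populations, needs = needs, profiles = profiles,
    cadres = cadres, hotel_costs = hotel_costs,
    shares = list(hospital = default_factor_shares("hospital"),
                  health_centre = default_factor_shares("health_centre")),
    program_costs = program_cost_spec(
      program_management = list(markup_fraction = 0.10),
      research = list(fixed_amount = 50000),
      monitoring_evaluation = list(markup_fraction = 0.02),
      communication_media_outreach = list(fixed_amount = 30000),
      training_above_facility = list(fixed_amount = 50000),
      infrastructure_equipment = list(markup_fraction = 0.05)))

  if (!is.null(dir)) {
    write_scenario(scn, dir)
    return(invisible(scn))
  }
  scn
}

#' Simulate facility cost records from a known translog process
#'
#' Log factor prices are drawn i.i.d. uniform on \[-0.5, 0.5\]; log output
#' volume is normal (output lognormal around 5000 services/year). Log total
#' cost follows the translog cost function whose first-order coefficients
#' equal the configured true shares (so the implied shares at the mean of the
#' log normalized prices, which is 0, equal `true_shares`), with a small
#' symmetric second-order block (entries of magnitude 0.01-0.02, so the
#' shares genuinely vary with prices) and an output elasticity of 0.9.
#' Multiplicative lognormal noise of standard deviation `noise_sd` is added
#' on the log scale. Per-factor expenditure columns (`exp_*`) are the implied
#' shares times total cost.
#'
#' @param config a [fixture_config()].
#' @param levels which facility levels to simulate.
#' @return data.frame of facility cost records (see [read_facilities()]),
#'   with a `true_params` attribute recording the generating coefficients
#'   per level.
#' @export
simulate_facility_costs <- function(config = fixture_config(),
                                    levels = c("hospital", "health_centre")) {
  set.seed(config$seed)
  gamma <- rbind(c( 0.02, -0.01, -0.01),
                 c(-0.01,  0.02, -0.01),
                 c(-0.01, -0.01,  0.02))
  delta_y <- 0.9
  beta0 <- 2
  out <- list()
  true_params <- list()
  for (lv in levels) {
    n <- config$n_facilities[[lv]]
    w <- config$true_shares[[lv]]
    beta <- w[1:3]
    lp <- matrix(stats::runif(n * 4L, -0.5, 0.5), nrow = n)  # log prices
    lny <- stats::rnorm(n, log(5000), 0.5)
    lpn <- lp[, 1:3] - lp[, 4L]  # log normalized prices
    lnC <- lp[, 4L] + beta0 + drop(lpn %*% beta) +
      0.5 * rowSums((lpn %*% gamma) * lpn) + delta_y * lny +
      stats::rnorm(n, 0, config$noise_sd)
    shares3 <- sweep(lpn %*% t(gamma), 2L, beta, "+")
    shares <- cbind(shares3, 1 - rowSums(shares3))
    total_cost <- exp(lnC)
    rec <- data.frame(
      facility_id = sprintf("%s_%04d", substr(lv, 1, 2), seq_len(n)),
      level = lv, total_cost = total_cost)
    prices <- exp(lp)
    for (i in 1:4) rec[[paste0("price_", FACTOR_NAMES[i])]] <- prices[, i]
    rec$output_volume <- exp(lny)
    for (i in 1:4) rec[[paste0("exp_", FACTOR_NAMES[i])]] <-
      shares[, i] * total_cost
    out[[lv]] <- rec
    true_params[[lv]] <- list(beta0 = beta0, beta = beta, gamma = gamma,
                              delta_y = delta_y, shares = w)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "true_params") <- true_params
  res
}
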