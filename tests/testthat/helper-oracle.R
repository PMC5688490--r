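# Independent brute-force oracles, written as plain loops over every
# (need row x channel x ingredient/time line) so they share no code path
# with the engine.

oracle_intervention_cost <- function(scn, id, year) {
  acc <- c(drugs_supplies = 0, labor = 0, other_direct = 0, indirect = 0)
  needs <- scn$needs
  for (r in seq_len(nrow(needs))) {
    if (needs$intervention_id[r] != id || needs$year[r] != year) next
    pop <- NA_real_
    for (p in seq_len(nrow(scn$populations))) {
      if (scn$populations$pop_id[p] == needs$pop_id[r] &&
          scn$populations$year[p] == year) {
        pop <- scn$populations$count[p]
      }
    }
    sv <- pop * needs$need_fraction[r] * needs$coverage_fraction[r]
    prof <- scn$profiles[[id]]
    for (ch in prof$channels) {
      w <- sv * ch$mix_fraction
      for (l in seq_len(nrow(ch$drug_lines))) {
        acc["drugs_supplies"] <- acc["drugs_supplies"] +
          w * ch$drug_lines$unit_price[l] * ch$drug_lines$units_per_case[l] *
          ch$drug_lines$pct_receiving[l]
      }
      for (l in seq_len(nrow(ch$time_lines))) {
        cd <- scn$cadres[scn$cadres$cadre_id == ch$time_lines$cadre_id[l], ]
        cpm <- cd$annual_remuneration /
          (cd$working_days_per_year * cd$minutes_per_day * cd$utilization)
        acc["labor"] <- acc["labor"] +
          w * ch$time_lines$minutes_per_visit[l] * ch$time_lines$n_visits[l] * cpm
      }
      opv_usd <- ch$visit_profile$opv_per_case * scn$hotel_costs$cost_per_opv
      ipd_usd <- ch$visit_profile$ipd_per_case * scn$hotel_costs$cost_per_ipd
      hc <- scn$shares$health_centre
      ho <- scn$shares$hospital
      acc["other_direct"] <- acc["other_direct"] +
        w * (opv_usd * hc[["other_direct"]] + ipd_usd * ho[["other_direct"]])
      acc["indirect"] <- acc["indirect"] +
        w * (opv_usd * hc[["indirect"]] + ipd_usd * ho[["indirect"]])
    }
  }
  acc
}

oracle_total_cost <- function(scn, year) {
  acc <- c(drugs_supplies = 0, labor = 0, other_direct = 0, indirect = 0)
  for (id in unique(scn$needs$intervention_id)) {
    acc <- acc + oracle_intervention_cost(scn, id, year)
  }
  above <- 0
  for (e in scn$program_costs) {
    above <- above + if (!is.null(e$fixed_amount)) e$fixed_amount
                     else e$markup_fraction * sum(acc)
  }
  c(acc, above_facility = above, total = sum(acc) + above)
}

# small random scenarios for oracle-equivalence checks
random_small_scenario <- function(seed) {
  set.seed(seed)
  years <- 2026:(2026 + sample(0:1, 1))
  n_int <- sample(1:5, 1)
  ids <- sprintf("i%02d", seq_len(n_int))
  pops <- c("popA", "popB")[seq_len(sample(1:2, 1))]
  populations <- expand.grid(pop_id = pops, year = years,
                             stringsAsFactors = FALSE)
  populations$count <- round(runif(nrow(populations), 1e4, 1e6))
  cadres <- data.frame(cadre_id = c("c1", "c2"),
                       annual_remuneration = runif(2, 2000, 30000),
                       working_days_per_year = c(220, 240),
                       minutes_per_day = 480,
                       utilization = runif(2, 0.4, 1))
  profiles <- list()
  needs <- list()
  for (id in ids) {
    n_chan <- sample(1:2, 1)
    mix <- if (n_chan == 1) 1 else {m <- runif(1, 0.2, 0.8); c(m, 1 - m)}
    chans <- list()
    for (ci in seq_len(n_chan)) {
      nd <- sample(0:3, 1)
      dl <- data.frame(item_id = sprintf("%s_it%d", id, seq_len(nd)),
                       unit_price = runif(nd, 0, 10),
                       units_per_case = sample(1:10, nd, replace = TRUE),
                       pct_receiving = runif(nd))
      nt <- sample(0:2, 1)
      tl <- data.frame(cadre_id = sample(cadres$cadre_id, nt),
                       minutes_per_visit = runif(nt, 1, 60),
                       n_visits = sample(1:5, nt, replace = TRUE))
      chans[[paste0("ch", ci)]] <- channel(
        drug_lines = dl, time_lines = tl,
        opv_per_case = round(runif(1, 0, 5), 2),
        ipd_per_case = round(runif(1, 0, 3), 2),
        mix_fraction = mix[ci])
    }
    profiles[[id]] <- intervention_profile(id, chans)
    needs[[id]] <- data.frame(
      intervention_id = id,
      pop_id = sample(pops, 1), year = years,
      need_fraction = runif(length(years), 0, 1.5),
      coverage_fraction = runif(length(years)))
  }
  scenario(name = sprintf("rand%d", seed), year_range = range(years),
           populations = populations, needs = do.call(rbind, needs),
           profiles = profiles, cadres = cadres,
           hotel_costs = list(cost_per_opv = runif(1, 0.5, 5),
                              cost_per_ipd = runif(1, 2, 25)),
           program_costs = program_cost_spec(
             program_management = list(markup_fraction = runif(1, 0, 0.2)),
             research = list(fixed_amount = runif(1, 0, 1e5))))
}

# Cobb-Douglas facility data: translog DGP with every second-order term zero
cobb_douglas_records <- function(n, beta, seed, noise_sd,
                                 level = "hospital", beta0 = 2, delta_y = 0.9) {
  set.seed(seed)
  lp <- matrix(runif(n * 4, -0.5, 0.5), nrow = n)
  lny <- rnorm(n, log(5000), 0.5)
  lpn <- lp[, 1:3] - lp[, 4]
  lnC <- lp[, 4] + beta0 + drop(lpn %*% beta) + delta_y * lny +
    rnorm(n, 0, noise_sd)
  rec <- data.frame(facility_id = sprintf("f%04d", seq_len(n)), level = level,
                    total_cost = exp(lnC))
  fn <- c("personnel", "consumables", "other_direct", "indirect")
  for (i in 1:4) rec[[paste0("price_", fn[i])]] <- exp(lp[, i])
  rec$output_volume <- exp(lny)
  rec
}

# scale every monetary input of a scenario (drug prices, wages, hotel costs)
scale_prices <- function(scn, k) {
  for (id in names(scn$profiles)) {
    for (chn in names(scn$profiles[[id]]$channels)) {
      scn$profiles[[id]]$channels[[chn]]$drug_lines$unit_price <-
        scn$profiles[[id]]$channels[[chn]]$drug_lines$unit_price * k
    }
  }
  scn$cadres$annual_remuneration <- scn$cadres$annual_remuneration * k
  scn$hotel_costs$cost_per_opv <- scn$hotel_costs$cost_per_opv * k
  scn$hotel_costs$cost_per_ipd <- scn$hotel_costs$cost_per_ipd * k
  scn
}
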