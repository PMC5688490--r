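test_that("services_count is the population x need x coverage product", {
  expect_equal(services_count(1e6, 0.20, 0.50), 1e5)
  expect_equal(services_count(123456, 0.7, 0), 0)
  # need fraction above 1: more than one case per person-year
  expect_equal(services_count(2e5, 1.5, 0.8), 240000)
  expect_error(services_count(-1, 0.5, 0.5), class = "costkit_domain_error")
  expect_error(services_count(10, -0.1, 0.5), class = "costkit_domain_error")
  expect_error(services_count(10, 0.5, 1.1), class = "costkit_domain_error")
})

test_that("cost_per_minute divides remuneration by productive minutes", {
  cadre <- list(annual_remuneration = 12000, working_days_per_year = 240,
                minutes_per_day = 480, utilization = 0.5)
  expect_equal(cost_per_minute(cadre), 12000 / 57600)
  expect_equal(cost_per_minute(list(annual_remuneration = 77,
                                    working_days_per_year = 1,
                                    minutes_per_day = 1, utilization = 1)), 77)
  cadre$utilization <- 0
  expect_error(cost_per_minute(cadre), class = "costkit_domain_error")
})

test_that("drug and supply cost per case follows the ingredients sum", {
  expect_equal(drug_supply_cost_per_case(
    data.frame(item_id = character(), unit_price = numeric(),
               units_per_case = numeric(), pct_receiving = numeric())), 0)
  one <- data.frame(item_id = "a", unit_price = 0.05, units_per_case = 10,
                    pct_receiving = 1)
  expect_equal(drug_supply_cost_per_case(one), 0.50)
  two <- rbind(one, data.frame(item_id = "b", unit_price = 2, units_per_case = 1,
                               pct_receiving = 0.5))
  expect_equal(drug_supply_cost_per_case(two), 1.50)
})

test_that("labor cost per case sums minutes x visits x cost per minute over cadres", {
  cadres <- data.frame(cadre_id = c("nurse", "doctor"),
                       annual_remuneration = c(12000, 48000),
                       working_days_per_year = 240, minutes_per_day = 480,
                       utilization = c(0.5, 0.8))
  tl <- data.frame(cadre_id = "nurse", minutes_per_visit = 20, n_visits = 3)
  expect_equal(labor_cost_per_case(tl, cadres), 60 * 12000 / 57600)  # 12.50
  expect_equal(labor_cost_per_case(tl, cadres), 12.5)

  tl0 <- transform(tl, n_visits = 0)
  expect_equal(labor_cost_per_case(tl0, cadres), 0)

  # two cadres sum independently: line-enumeration oracle
  set.seed(99)
  tl2 <- data.frame(cadre_id = c("nurse", "doctor", "nurse"),
                    minutes_per_visit = runif(3, 1, 60),
                    n_visits = sample(1:4, 3, replace = TRUE))
  oracle <- 0
  for (l in seq_len(nrow(tl2))) {
    cd <- cadres[cadres$cadre_id == tl2$cadre_id[l], ]
    oracle <- oracle + tl2$minutes_per_visit[l] * tl2$n_visits[l] *
      cd$annual_remuneration /
      (cd$working_days_per_year * cd$minutes_per_day * cd$utilization)
  }
  expect_equal(labor_cost_per_case(tl2, cadres), oracle)

  expect_error(labor_cost_per_case(transform(tl, cadre_id = "ghost"), cadres),
               class = "costkit_validation_error")
})

test_that("hotel overhead applies only the ODC and indirect share of OPV/IPD costs", {
  sh_h <- default_factor_shares("hospital")
  sh_c <- default_factor_shares("health_centre")
  hotel <- list(cost_per_opv = 2, cost_per_ipd = 10)

  # OPV-only case uses health-centre shares: 8 x 0.085, 8 x 0.290
  ov <- hotel_overhead_per_case(list(opv_per_case = 4, ipd_per_case = 0),
                                hotel, sh_h, sh_c)
  expect_equal(unname(ov), c(0.68, 2.32))

  # IPD-only case uses hospital shares: 10 x 0.098, 10 x 0.195
  ov <- hotel_overhead_per_case(list(opv_per_case = 0, ipd_per_case = 1),
                                hotel, sh_h, sh_c)
  expect_equal(unname(ov), c(0.98, 1.95))

  ov <- hotel_overhead_per_case(list(opv_per_case = 0, ipd_per_case = 0),
                                hotel, sh_h, sh_c)
  expect_equal(unname(ov), c(0, 0))
})

test_that("unit cost per case composes components and weights by channel mix", {
  cadres <- data.frame(cadre_id = "nurse", annual_remuneration = 12000,
                       working_days_per_year = 240, minutes_per_day = 480,
                       utilization = 0.5)
  db <- list(cadres = cadres,
             hotel_costs = list(cost_per_opv = 2, cost_per_ipd = 10),
             shares = list(hospital = default_factor_shares("hospital"),
                           health_centre = default_factor_shares("health_centre")))
  dl <- data.frame(item_id = "a", unit_price = 0.05, units_per_case = 10,
                   pct_receiving = 1)
  tl <- data.frame(cadre_id = "nurse", minutes_per_visit = 20, n_visits = 3)
  ch1 <- channel(dl, tl, opv_per_case = 4, ipd_per_case = 0, mix_fraction = 1)
  u <- unit_cost_per_case(intervention_profile("i1", list(f = ch1)), db)
  expect_equal(unname(u), c(0.50, 12.50, 0.68, 2.32))

  # 0.5/0.5 mix of a channel and an all-zero channel halves every component
  ch_a <- channel(dl, tl, opv_per_case = 4, mix_fraction = 0.5)
  ch_0 <- channel(mix_fraction = 0.5)
  u2 <- unit_cost_per_case(intervention_profile("i1", list(a = ch_a, z = ch_0)),
                           db)
  expect_equal(unname(u2), unname(u) / 2)

  u0 <- unit_cost_per_case(intervention_profile("i1", list(z = channel())), db)
  expect_equal(unname(u0), c(0, 0, 0, 0))
})

test_that("intervention cost scales unit costs by services and errors on unknowns", {
  scn <- generate_country_fixture(fixture_config(seed = 42))
  id <- "intv_01"
  b <- intervention_cost(scn, id, 2027)
  u <- unit_cost_per_case(scn$profiles[[id]], cost_db(scn))
  rows <- scn$needs[scn$needs$intervention_id == id & scn$needs$year == 2027, ]
  pop <- merge(rows, scn$populations)
  sv <- sum(pop$count * pop$need_fraction * pop$coverage_fraction)
  expect_equal(unname(unclass(b)[1:4]), unname(u * sv))

  # zero coverage everywhere gives a zero breakdown
  scn0 <- scn
  scn0$needs$coverage_fraction <- 0
  expect_equal(unname(unclass(intervention_cost(scn0, id, 2027))), rep(0, 6))

  expect_error(intervention_cost(scn, "ghost", 2027),
               class = "costkit_validation_error")
  expect_error(intervention_cost(scn, id, 1999),
               class = "costkit_validation_error")
})

test_that("program costs pass amounts through and apply markups to the facility total", {
  expect_equal(program_costs(program_cost_spec(), 1e6)$total, 0)
  spec <- program_cost_spec(program_management = list(markup_fraction = 0.10))
  expect_equal(program_costs(spec, 1e6)$categories[["program_management"]], 1e5)
  mixed <- program_cost_spec(
    training_above_facility = list(fixed_amount = 5e4),
    monitoring_evaluation = list(markup_fraction = 0.02))
  expect_equal(program_costs(mixed, 1e6)$total, 7e4)
  expect_error(program_costs(spec, -1), class = "costkit_domain_error")
})

test_that("engine totals equal the brute-force enumeration oracle on random scenarios", {
  for (seed in 1:10) {
    scn <- random_small_scenario(seed)
    for (yr in scenario_years(scn)) {
      expect_equal(unclass(total_cost(scn, yr)), oracle_total_cost(scn, yr),
                   tolerance = 1e-11)
    }
  }
})

test_that("total cost conserves components, is linear in prices, monotone in coverage", {
  scn <- generate_country_fixture(fixture_config(seed = 42))
  res <- cost_summary(scn)
  sums <- res$drugs_supplies + res$labor + res$other_direct + res$indirect +
    res$above_facility
  expect_equal(res$total, sums, tolerance = 1e-12)

  # doubling every price, wage and hotel cost exactly doubles facility costs
  b1 <- unclass(total_cost(scn, 2028))
  b2 <- unclass(total_cost(scale_prices(scn, 2), 2028))
  fac <- c("drugs_supplies", "labor", "other_direct", "indirect")
  expect_identical(b2[fac], 2 * b1[fac])

  # scaling populations scales facility components linearly
  scn_p <- scn
  scn_p$populations$count <- scn_p$populations$count * 3
  b3 <- unclass(total_cost(scn_p, 2028))
  expect_equal(b3[fac], 3 * b1[fac], tolerance = 1e-12)

  # raising any coverage never lowers the total
  scn_c <- scn
  scn_c$needs$coverage_fraction <- pmin(1, scn_c$needs$coverage_fraction + 0.1)
  expect_gte(total_cost(scn_c, 2028)[["total"]], b1[["total"]])

  scn_n <- scn
  scn_n$needs$need_fraction <- scn_n$needs$need_fraction * 1.5
  expect_gte(total_cost(scn_n, 2028)[["total"]], b1[["total"]])
})

test_that("costing consumes only the ODC and indirect shares, never personnel/consumables", {
  scn <- generate_country_fixture(fixture_config(seed = 42))
  ref <- total_cost(scn, 2027)
  # arbitrary personnel/consumables shares (same row sum) leave outputs unchanged
  scn2 <- scn
  scn2$shares$hospital <- factor_shares(0.60, 0.107, 0.098, 0.195, "hospital")
  scn2$shares$health_centre <- factor_shares(0.10, 0.494, 0.085, 0.290,
                                             "health_centre")
  expect_identical(total_cost(scn2, 2027), ref)
})
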