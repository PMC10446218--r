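test_that("discount factors follow the annualized power law", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(17, 0), 1)
  # a whole year of cycles at 3%: cycle_days * k = 365.25 with k = 365.25/21
  expect_equal(discount_factor(365.25 / 21, 0.03), 1 / 1.03)
  expect_error(discount_factor(3, -0.01), ">= 0")
})

test_that("per-cycle drug costs follow dose, pack size and schedule", {
  sc <- paper_fixture("whole_group")
  dcn <- cycle_drug_cost(sc$strategies$nc$costs)
  # 240 mg daily in 40 mg units: 6 x 13.46 x 21 days
  expect_equal(dcn$by_drug$cost_per_cycle[dcn$by_drug$drug == "neratinib"],
               6 * 13.46 * 21)
  # 1500 mg/m2 x 1.67 m2 = 2505 mg -> 17 x 150 mg units, twice daily x 14
  expect_equal(dcn$by_drug$units[dcn$by_drug$drug == "capecitabine"], 17)
  expect_equal(dcn$by_drug$cost_per_cycle[dcn$by_drug$drug == "capecitabine"],
               17 * 0.6 * 2 * 14)
  expect_equal(dcn$total, 1695.96 + 285.60)
  dcl <- cycle_drug_cost(sc$strategies$lc$costs)
  expect_equal(dcl$total, 5 * 16.12 * 21 + 23 * 0.6 * 2 * 14)
  # zero dose accrues nothing
  cs <- sc$strategies$nc$costs
  cs$dosing$dose_mg <- 0
  expect_equal(cycle_drug_cost(cs)$total, 0)
})

test_that("antidiarrheal prophylaxis cost counts the scheduled tablets", {
  lp <- list(unit_mg = 2, unit_price_usd = 0.23, initial_mg = 4,
             loading_interval_h = 4, loading_days = 3,
             maintenance_interval_h = 6)
  expect_equal(loperamide_prophylaxis_cost(lp), 92 * 0.23)  # 21.16
  lp$maintenance_interval_h <- 8
  expect_equal(loperamide_prophylaxis_cost(lp), 74 * 0.23)  # 17.02
  lp$unit_price_usd <- 0
  expect_equal(loperamide_prophylaxis_cost(lp), 0)
  expect_equal(loperamide_prophylaxis_cost(NULL), 0)
})

test_that("expected adverse-event cost is the incidence-weighted sum", {
  sc <- paper_fixture("whole_group")
  expect_equal(expected_ae_cost(sc$strategies$nc$costs$ae_profile),
               0.307 * 4083.63 + 0.120 * 2316 + 0.050 * 945.63 +
                 0.037 * 1158.04 + 0.024 * 7350.98)
  zero <- data.frame(event = "x", incidence = 0, cost_per_event = 1000)
  expect_equal(expected_ae_cost(zero), 0)
  one <- data.frame(event = "x", incidence = 1, cost_per_event = 123.4)
  expect_equal(expected_ae_cost(one), 123.4)
})

test_that("occupancy is conserved and an identity matrix freezes the cohort", {
  s <- short_settings(20)
  idm <- diag(4); dimnames(idm) <- list(STATES, STATES)
  acc <- list(state_cost = c(SD = 1, RE = 1, PD = 1, DE = 0),
              state_utility = c(SD = 1, RE = 0.8, PD = 0.5, DE = 0),
              one_time_cost = 0)
  tr <- run_cohort(idm, acc, s)
  expect_true(all(tr$occupancy[, "SD"] == 1))
  set.seed(42)
  for (i in 1:25) {
    m <- random_stochastic_matrix()
    tr <- run_cohort(m, acc, s)
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, nrow(tr$occupancy)),
                 tolerance = 1e-10)
  }
  # all-death matrix absorbs everyone after one cycle
  kill <- matrix(0, 4, 4); kill[, 4] <- 1
  dimnames(kill) <- list(STATES, STATES)
  tr <- run_cohort(kill, acc, s)
  expect_equal(tr$occupancy[-1, "DE"], setNames(rep(1, 20), 1:20))
})

test_that("engine totals match the matrix-power oracle", {
  acc_names <- STATES
  set.seed(2024)
  for (i in 1:60) {
    m <- random_stochastic_matrix()
    n_cyc <- sample(2:10, 1)
    rate <- runif(1, 0, 0.1)
    conv <- sample(c("half_cycle", "start", "end"), 1)
    s <- short_settings(n_cyc, rate = rate)
    state_cost <- setNames(runif(4, 0, 500), acc_names)
    state_ut <- setNames(runif(4), acc_names)
    one_time <- runif(1, 0, 100)
    acc <- list(state_cost = state_cost, state_utility = state_ut,
                one_time_cost = one_time)
    got <- run_cohort(m, acc, s, convention = conv)$totals
    want <- oracle_totals(m, s$initial_distribution, state_cost, state_ut,
                          one_time, n_cyc, rate, 21, conv)
    expect_equal(got$total_cost, want$total_cost, tolerance = 1e-10)
    expect_equal(got$total_qaly, want$total_qaly, tolerance = 1e-10)
  }
})

test_that("a two-state survival chain reproduces the geometric closed form", {
  p <- 0.07
  m <- diag(4); dimnames(m) <- list(STATES, STATES)
  m["SD", "SD"] <- 1 - p
  m["SD", "DE"] <- p
  n_cyc <- 40
  s <- short_settings(n_cyc, rate = 0, hcc = FALSE)
  acc <- list(state_cost = c(SD = 0, RE = 0, PD = 0, DE = 0),
              state_utility = c(SD = 1, RE = 0, PD = 0, DE = 0),
              one_time_cost = 0)
  tr <- run_cohort(m, acc, s, convention = "start")
  cycle_years <- 21 / 365.25
  expect_equal(tr$totals$total_qaly,
               (1 - (1 - p)^n_cyc) / p * cycle_years, tolerance = 1e-9)
})

test_that("death occupancy never decreases and accruals are non-negative", {
  set.seed(9)
  for (i in 1:20) {
    sc <- generate_scenario(seed = i)
    for (st in sc$strategies) {
      tr <- run_strategy(st, sc$settings)
      expect_true(all(diff(tr$occupancy[, "DE"]) >= -1e-12))
      expect_true(all(tr$per_cycle_cost >= 0))
      expect_true(all(tr$per_cycle_qaly >= 0))
    }
  }
})

test_that("discounting can only shrink totals", {
  sc <- paper_fixture("whole_group")
  tr_disc <- run_strategy(sc$strategies$nc, sc$settings)
  s0 <- sc$settings
  s0$annual_discount_rate <- 0
  tr_undisc <- run_strategy(sc$strategies$nc, s0)
  expect_lt(tr_disc$totals$total_cost, tr_undisc$totals$total_cost)
  expect_lt(tr_disc$totals$total_qaly, tr_undisc$totals$total_qaly)
})

test_that("half-cycle totals lie between start- and end-of-cycle counting", {
  sc <- paper_fixture("whole_group")
  st <- sc$strategies$nc
  tm <- build_matrix(st$clinical)
  acc <- build_accrual(st, sc$settings)
  tot <- function(conv)
    run_cohort(tm, acc, sc$settings, convention = conv)$totals$total_qaly
  q <- c(start = tot("start"), half = tot("half_cycle"), end = tot("end"))
  expect_true(q["end"] <= q["half"] && q["half"] <= q["start"])
})

test_that("raising a utility or overall survival weakly raises QALYs", {
  sc <- paper_fixture("whole_group")
  base <- run_strategy(sc$strategies$nc, sc$settings)$totals$total_qaly
  up <- sc$strategies$nc
  up$utilities$relapse <- 0.6
  expect_gt(run_strategy(up, sc$settings)$totals$total_qaly, base)
  longer <- sc$strategies$nc
  longer$clinical <- clinical_summary(os_months = 30, pfs_months = 8.8,
                                      dor_months = 8.5)
  expect_gt(run_strategy(longer, sc$settings)$totals$total_qaly, base)
})

test_that("accrual map prices states according to the documented defaults", {
  sc <- paper_fixture("whole_group")
  acc <- build_accrual(sc$strategies$nc, sc$settings)
  cyc <- 21 / 365.25
  drug <- cycle_drug_cost(sc$strategies$nc$costs)$total
  expect_equal(unname(acc$state_cost["SD"]), drug + 4552 * cyc)
  expect_equal(unname(acc$state_cost["RE"]), 4552 * cyc)
  expect_equal(unname(acc$state_cost["PD"]), (3200 + 2176) * cyc)
  expect_equal(unname(acc$state_cost["DE"]), 0)
  expect_equal(unname(acc$state_utility), c(0.74, 0.85, 0.5, 0))
  expect_equal(acc$one_time_cost,
               expected_ae_cost(sc$strategies$nc$costs$ae_profile) + 21.16)
})

test_that("cohort trace exports tidily", {
  sc <- paper_fixture("whole_group")
  tr <- run_strategy(sc$strategies$nc, sc$settings)
  df <- trace_to_df(tr)
  expect_equal(nrow(df), 4 * (n_cycles(sc$settings) + 1))
  expect_equal(sum(df$occupancy), nrow(tr$occupancy))
})

test_that("run_cohort rejects non-stochastic matrices", {
  bad <- matrix(0.3, 4, 4)
  acc <- list(state_cost = setNames(rep(0, 4), STATES),
              state_utility = setNames(rep(1, 4), STATES),
              one_time_cost = 0)
  expect_error(run_cohort(bad, acc, short_settings(5)), "sum to 1")
})
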