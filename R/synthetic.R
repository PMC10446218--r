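## Random but structurally valid scenario generation, plus stress cases.
## Used throughout the test suite so every pipeline stage can be exercised
## on inputs with the same statistical structure as the published tables:
## two arms sharing unit prices, per-event costs and utilities, differing in
## clinical summaries, dosing and adverse-event incidences.

synth_clinical <- function(os_range, pfs_frac_range, dor_frac_range, dor_min) {
  os <- runif(1, os_range[1], os_range[2])
  # PFS as a fraction of OS guarantees OS > PFS structurally
  pfs <- os * runif(1, pfs_frac_range[1], pfs_frac_range[2])
  # DoR floor keeps 4*p_rp + p_sr < 1 for any rr in (0,1), since
  # p_sr < 1 - exp(-1/3) = 0.284 always: derived rows stay stochastic
  dor <- max(dor_min, pfs * runif(1, dor_frac_range[1], dor_frac_range[2]))
  clinical_summary(os_months = os, pfs_months = pfs, dor_months = dor)
}

synth_cost_pool <- function() {
  list(prices = c(agent_a = round(runif(1, 5, 25), 2),
                  agent_b = round(runif(1, 5, 25), 2),
                  backbone = round(runif(1, 0.3, 2), 2)),
       ae_costs = c(toxicity_a = round(runif(1, 2000, 8000), 2),
                    toxicity_b = round(runif(1, 800, 3000), 2),
                    toxicity_c = round(runif(1, 500, 1500), 2)),
       other = c(hospitalization = round(runif(1, 1500, 5000), 2),
                 concomitant_medications = round(runif(1, 800, 3000), 2),
                 health_examinations = round(runif(1, 2000, 6000), 2)))
}

synth_costs <- function(pool, agent, with_prophylaxis) {
  dosing <- data.frame(
    drug = c(agent, "backbone"),
    dose_mg = c(round(runif(1, 100, 1500)), round(runif(1, 500, 2500))),
    per_m2 = c(FALSE, TRUE),
    unit_mg = c(50, 150),
    unit_price_usd = as.numeric(pool$prices[c(agent, "backbone")]),
    admin_per_day = c(1, 2),
    days_per_cycle = c(21, 14))
  ae <- data.frame(event = names(pool$ae_costs),
                   incidence = round(runif(3, 0.01, 0.35), 3),
                   cost_per_event = as.numeric(pool$ae_costs))
  lop <- if (with_prophylaxis) fixture_loperamide() else NULL
  cost_schedule(dosing, ae, pool$other, loperamide = lop)
}

synth_shared_ranges <- function(utils, pool, discount_rate, strategies) {
  rng <- list(
    u_stable = pct_range(utils$stable, 0.20, clamp01 = TRUE),
    u_remission = pct_range(utils$remission, 0.20, clamp01 = TRUE),
    u_relapse = pct_range(utils$relapse, 0.20, clamp01 = TRUE),
    discount_rate = pct_range(discount_rate, 0.10))
  used <- unique(unlist(lapply(strategies, function(s) s$costs$dosing$drug)))
  for (nm in intersect(names(pool$prices), used))
    rng[[paste0("price_", nm)]] <- pct_range(pool$prices[[nm]])
  if (any(vapply(strategies, function(s) !is.null(s$costs$loperamide), TRUE)))
    rng[["price_loperamide"]] <- pct_range(fixture_loperamide()$unit_price_usd)
  for (nm in names(pool$ae_costs))
    rng[[paste0("cost_ae_", nm)]] <- pct_range(pool$ae_costs[[nm]])
  for (nm in names(pool$other))
    rng[[paste0("cost_", nm)]] <- pct_range(pool$other[[nm]])
  rng
}

#' Generate a random, structurally valid two-arm scenario
#'
#' Draws clinical summaries (PFS as a uniform fraction of OS so `OS > PFS`
#' holds by construction; DoR floored so every derived transition row is
#' stochastic), a shared cost pool (unit prices, per-event adverse-event
#' costs, recurring non-drug costs), per-arm dosing and incidences, and
#' utilities with plausible ordering (remission best, progressive disease
#' worst). Sensitivity ranges are auto-generated: +/-10% for probabilities
#' and costs (clamped to \[0, 1\] for probabilities), +/-20% for utilities.
#' Reproducible under `seed`.
#'
#' @param seed Integer RNG seed.
#' @param os_range Months; default 12–40.
#' @param pfs_frac_range PFS as a fraction of OS; default 0.2–0.8. Must lie
#'   strictly inside (0, 1).
#' @param dor_frac_range DoR as a fraction of PFS; default 0.5–2.
#' @param dor_min Floor on DoR, months; default 2.7 (keeps
#'   `4 * p_rp + p_sr < 1` for every attainable risk fraction).
#' @param identical_arms If `TRUE` the second arm is a copy of the first
#'   (downstream increments are exactly zero).
#' @return A [ce_scenario()].
#' @export
generate_scenario <- function(seed, os_range = c(12, 40),
                              pfs_frac_range = c(0.2, 0.8),
                              dor_frac_range = c(0.5, 2), dor_min = 2.7,
                              identical_arms = FALSE) {
  if (pfs_frac_range[1] <= 0 || pfs_frac_range[2] >= 1)
    stop_domain("pfs_frac_range must lie strictly inside (0, 1) to keep OS > PFS")
  set.seed(as.integer(seed))
  u_re <- runif(1, 0.7, 0.95)
  u_sd <- runif(1, 0.5, u_re)
  u_pd <- runif(1, 0.2, u_sd)
  utils <- utility_set(stable = u_sd, remission = u_re, relapse = u_pd)
  pool <- synth_cost_pool()
  mk_arm <- function(id, name, agent, with_prophylaxis) {
    st <- strategy_inputs(id, name,
                          synth_clinical(os_range, pfs_frac_range,
                                         dor_frac_range, dor_min),
                          synth_costs(pool, agent, with_prophylaxis), utils)
    auto_sa_ranges(st)
  }
  a <- mk_arm("arm_a", "Arm A", "agent_a", with_prophylaxis = TRUE)
  b <- if (identical_arms) {
    b2 <- a
    b2$id <- "arm_b"; b2$name <- "Arm B"
    b2
  } else mk_arm("arm_b", "Arm B", "agent_b", with_prophylaxis = FALSE)
  settings <- model_settings()
  ce_scenario(name = sprintf("synthetic_%d", as.integer(seed)),
              strategies = list(a, b), settings = settings,
              shared_ranges = synth_shared_ranges(
                utils, pool, settings$annual_discount_rate, list(a, b)))
}

#' Boundary and stress-case scenarios
#'
#' A named list of deliberately extreme but valid scenarios:
#' `near_immortal` (huge post-progression survival: almost nobody dies
#' within the horizon), `near_instant_death` (post-progression survival of
#' days), `relapse_boundary` (remission-to-relapse probability just under
#' the 0.25 limit at which the 4x stable-relapse rule would exceed 1),
#' `zero_cost` (all prices and costs zero in both arms: total cost is
#' exactly the one-time entry cost, itself zero) and `full_utility`
#' (utility 1 everywhere, no discounting, essentially no death: total QALYs
#' equal the modelled horizon).
#'
#' @return Named list of [ce_scenario()] objects.
#' @export
generate_edge_cases <- function() {
  base <- generate_scenario(seed = 1L)
  tweak <- function(sc, os, pfs, dor, arm = "arm_a") {
    sc$strategies[[arm]]$clinical <-
      clinical_summary(os_months = os, pfs_months = pfs, dor_months = dor)
    sc$strategies[[arm]] <- auto_sa_ranges(sc$strategies[[arm]])
    validate_scenario(sc)
  }
  zero_cost <- base
  for (id in names(zero_cost$strategies)) {
    st <- zero_cost$strategies[[id]]
    st$costs$dosing$unit_price_usd <- 0
    st$costs$ae_profile$cost_per_event <- 0
    st$costs$other_costs[] <- 0
    st$costs$loperamide <- NULL
    zero_cost$strategies[[id]] <- auto_sa_ranges(st)
  }
  zero_cost$shared_ranges <-
    zero_cost$shared_ranges[grepl("^u_|^discount", names(zero_cost$shared_ranges))]

  full_utility <- tweak(base, os = 1e6, pfs = 12, dor = 1e6)
  for (id in names(full_utility$strategies))
    full_utility$strategies[[id]]$utilities <-
      utility_set(stable = 1, remission = 1, relapse = 1)
  full_utility$settings$annual_discount_rate <- 0
  full_utility$shared_ranges[c("u_stable", "u_remission", "u_relapse")] <-
    list(c(1, 1), c(1, 1), c(1, 1))
  full_utility$shared_ranges[["discount_rate"]] <- c(0, 0)

  list(
    near_immortal = tweak(base, os = 1200, pfs = 12, dor = 24),
    near_instant_death = tweak(base, os = 10.1, pfs = 10, dor = 3),
    relapse_boundary = tweak(base, os = 2000, pfs = 1999, dor = 1.80825),
    zero_cost = validate_scenario(zero_cost),
    full_utility = validate_scenario(full_utility))
}
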