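#' @importFrom stats rbeta rgamma runif setNames
#' @importFrom utils write.csv packageVersion
NULL

#' Health-state codes of the cohort model
#'
#' The model has four states: stable disease (`SD`, on active chemotherapy),
#' remission (`RE`, responding, off intensive treatment), progressive /
#' relapsed disease (`PD`) and death (`DE`, absorbing). All occupancy vectors
#' and transition matrices are ordered this way.
#'
#' @format Character vector of length 4.
#' @export
STATES <- c("SD", "RE", "PD", "DE")

stop_domain <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain("'%s' must be a single finite number", name)
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok)
    stop_domain("'%s' = %g is outside its valid range %s%g, %g%s", name, x,
                if (strict_min) "(" else "[", min, max,
                if (strict_max) ")" else "]")
  invisible(x)
}

#' Clinical efficacy summary for one treatment arm
#'
#' Bundles the median survival summaries that drive all transition
#' probabilities: overall survival (OS), progression-free survival (PFS) and
#' duration of response (DoR), in months, plus the response-derived risk
#' fraction `rr = (OS - PFS) / OS`. When `rr` is not supplied it is derived
#' from the medians via [derive_rr()]; supplying it explicitly allows a
#' published (rounded) value to be carried verbatim.
#'
#' @param os_months Median overall survival, months. Must exceed `pfs_months`.
#' @param pfs_months Median progression-free survival, months (> 0).
#' @param dor_months Median duration of response, months (> 0).
#' @param rr Optional risk fraction in (0, 1); defaults to
#'   `(os_months - pfs_months) / os_months`.
#' @return An object of class `clinical_summary`.
#' @examples
#' clinical_summary(os_months = 24, pfs_months = 8.8, dor_months = 8.5, rr = 0.63)
#' @export
clinical_summary <- function(os_months, pfs_months, dor_months, rr = NULL) {
  check_number(pfs_months, "pfs_months", min = 0, strict_min = TRUE)
  check_number(os_months, "os_months", min = 0, strict_min = TRUE)
  if (os_months <= pfs_months)
    stop_domain("os_months (%g) must exceed pfs_months (%g)",
                os_months, pfs_months)
  check_number(dor_months, "dor_months", min = 0, strict_min = TRUE)
  if (is.null(rr)) {
    rr <- (os_months - pfs_months) / os_months
  } else {
    check_number(rr, "rr", min = 0, max = 1, strict_min = TRUE,
                 strict_max = TRUE)
    implied <- (os_months - pfs_months) / os_months
    if (abs(rr - implied) > 0.015)
      warning(sprintf(
        "supplied rr = %g differs from (OS-PFS)/OS = %.4f by more than 0.015",
        rr, implied), call. = FALSE)
  }
  structure(list(rr = rr, os_months = os_months, pfs_months = pfs_months,
                 dor_months = dor_months),
            class = "clinical_summary")
}

#' Health-state utility weights
#'
#' Utility weights on the 0 (death) to 1 (full health) scale for the four
#' model states. Death is fixed at 0. Extra published utilities with no
#' corresponding model state (e.g. post-chemotherapy no-recurrence) can be
#' carried in `extras` for completeness; they do not enter the QALY accrual.
#'
#' @param stable Utility while in stable disease (the chemotherapeutic
#'   period), default 0.74.
#' @param remission Utility in remission, default 0.85.
#' @param relapse Utility in progressive disease, default 0.5.
#' @param death Must be 0.
#' @param extras Named list of additional utilities, each in \[0, 1\].
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(stable = 0.74, remission = 0.85, relapse = 0.5,
                        death = 0, extras = list()) {
  check_number(stable, "stable", 0, 1)
  check_number(remission, "remission", 0, 1)
  check_number(relapse, "relapse", 0, 1)
  if (!identical(as.numeric(death), 0))
    stop_domain("the death-state utility is fixed at 0 (got %g)", death)
  for (nm in names(extras)) check_number(extras[[nm]], nm, 0, 1)
  structure(list(stable = stable, remission = remission, relapse = relapse,
                 death = 0, extras = extras),
            class = "utility_set")
}

#' Per-arm cost schedule
#'
#' Everything needed to price one treatment arm: the drug dosing table with
#' unit prices (2022 USD), the grade-3/4 adverse-event profile (incidence and
#' per-event management cost), recurring non-drug costs, and the body-surface
#' area used to convert per-m2 doses to absolute doses.
#'
#' @param dosing Data frame with columns `drug`, `dose_mg` (per
#'   administration; per m2 of body surface when `per_m2` is `TRUE`),
#'   `per_m2` (logical), `unit_mg` (pack/tablet strength), `unit_price_usd`,
#'   `admin_per_day`, `days_per_cycle`. Units dispensed per administration
#'   are `ceiling(dose / unit_mg)` (no tablet splitting).
#' @param ae_profile Data frame with columns `event`, `incidence` (fraction
#'   in \[0,1\]), `cost_per_event` (USD).
#' @param other_costs Named numeric: `hospitalization`,
#'   `concomitant_medications` (accrued in progressive disease) and
#'   `health_examinations` (accrued in stable disease and remission), each an
#'   amount per `other_cost_period`.
#' @param bsa_m2 Body surface area, m2; default 1.67.
#' @param loperamide Optional antidiarrheal prophylaxis schedule (see
#'   [loperamide_prophylaxis_cost()]); `NULL` when the arm has none.
#' @param other_cost_period Accrual period of `other_costs`: `"per_year"`
#'   (default, converted to per-cycle by `cycle_days / 365.25`) or
#'   `"per_cycle"`.
#' @param drug_states States in which drug acquisition cost accrues; default
#'   `"SD"` (the chemotherapeutic period).
#' @return An object of class `cost_schedule`.
#' @export
cost_schedule <- function(dosing, ae_profile, other_costs, bsa_m2 = 1.67,
                          loperamide = NULL,
                          other_cost_period = c("per_year", "per_cycle"),
                          drug_states = "SD") {
  other_cost_period <- match.arg(other_cost_period)
  dosing <- as.data.frame(dosing)
  need <- c("drug", "dose_mg", "per_m2", "unit_mg", "unit_price_usd",
            "admin_per_day", "days_per_cycle")
  miss <- setdiff(need, names(dosing))
  if (length(miss))
    stop_domain("dosing table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(dosing$unit_price_usd < 0)) stop_domain("drug unit prices must be >= 0")
  if (any(dosing$dose_mg < 0) || any(dosing$unit_mg <= 0))
    stop_domain("doses must be >= 0 and unit strengths > 0")
  ae_profile <- as.data.frame(ae_profile)
  miss <- setdiff(c("event", "incidence", "cost_per_event"), names(ae_profile))
  if (length(miss))
    stop_domain("ae_profile lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(ae_profile$incidence < 0 | ae_profile$incidence > 1))
    stop_domain("adverse-event incidences must lie in [0, 1]")
  if (any(ae_profile$cost_per_event < 0))
    stop_domain("adverse-event costs must be >= 0")
  other_costs <- unlist(other_costs)
  if (any(other_costs < 0)) stop_domain("other_costs must be >= 0")
  check_number(bsa_m2, "bsa_m2", min = 0, strict_min = TRUE)
  if (!all(drug_states %in% STATES[1:3]))
    stop_domain("drug_states must be a subset of SD/RE/PD")
  structure(list(dosing = dosing, ae_profile = ae_profile,
                 other_costs = other_costs, bsa_m2 = bsa_m2,
                 loperamide = loperamide,
                 other_cost_period = other_cost_period,
                 drug_states = drug_states),
            class = "cost_schedule")
}

#' One treatment strategy (arm) of the model
#'
#' @param id Short machine identifier (used to prefix the arm's entries in
#'   the sensitivity-analysis parameter table, e.g. `"nc"` gives
#'   `"nc.p_rp"`).
#' @param name Display name, e.g. `"N+C"`.
#' @param clinical A [clinical_summary()].
#' @param costs A [cost_schedule()].
#' @param utilities A [utility_set()].
#' @param sa_ranges Named list of `c(low, high)` sensitivity ranges for this
#'   arm's parameters (`p_ss`, `p_sr`, `p_sp`, `p_rr`, `p_rp`, `p_pp`,
#'   `p_pd`, `inc_<event>`). Every range must contain the parameter's base
#'   value.
#' @param prob_overrides Named numeric overriding derived per-cycle
#'   probabilities (`p_sr`, `p_sp`, `p_rp`, `p_pd`); used internally by the
#'   sensitivity machinery.
#' @return An object of class `strategy_inputs`.
#' @export
strategy_inputs <- function(id, name, clinical, costs, utilities,
                            sa_ranges = list(), prob_overrides = NULL) {
  stopifnot(inherits(clinical, "clinical_summary"),
            inherits(costs, "cost_schedule"),
            inherits(utilities, "utility_set"))
  if (!grepl("^[a-z][a-z0-9_]*$", id))
    stop_domain("strategy id '%s' must be a lowercase identifier", id)
  structure(list(id = id, name = name, clinical = clinical, costs = costs,
                 utilities = utilities, sa_ranges = sa_ranges,
                 prob_overrides = prob_overrides),
            class = "strategy_inputs")
}

#' Global model settings
#'
#' @param cycle_days Markov cycle length in days (default 21, one
#'   chemotherapy cycle).
#' @param horizon_years Time horizon in years (default 5). The number of
#'   cycles is `floor(horizon_years * 365.25 / cycle_days)` so the horizon is
#'   never exceeded.
#' @param annual_discount_rate Annual discount rate for both costs and QALYs
#'   (default 0.03).
#' @param wtp_per_qaly Willingness-to-pay threshold, USD per QALY (default
#'   36000 = 3x Chinese per-capita GDP in 2022).
#' @param gdp_per_capita Per-capita GDP used by the decision-tier rule
#'   (default 12000).
#' @param initial_distribution Named cohort fractions over
#'   `c("SD","RE","PD","DE")` at model entry; must sum to 1. Default: the
#'   whole cohort starts in stable disease.
#' @param half_cycle_correction Apply trapezoidal (Sonnenberg-Beck)
#'   state-membership weighting? Default `TRUE`.
#' @param rounding_mode `"full_precision"` (default) keeps derived transition
#'   probabilities unrounded; `"paper_3dp"` rounds each derived probability
#'   to 3 decimals before complements and multiples are formed, reproducing
#'   published tables.
#' @return An object of class `model_settings`.
#' @export
model_settings <- function(cycle_days = 21, horizon_years = 5,
                           annual_discount_rate = 0.03,
                           wtp_per_qaly = 36000, gdp_per_capita = 12000,
                           initial_distribution = c(SD = 1, RE = 0, PD = 0, DE = 0),
                           half_cycle_correction = TRUE,
                           rounding_mode = c("full_precision", "paper_3dp")) {
  rounding_mode <- match.arg(rounding_mode)
  check_number(cycle_days, "cycle_days", min = 1)
  check_number(horizon_years, "horizon_years", min = 0, strict_min = TRUE)
  check_number(annual_discount_rate, "annual_discount_rate", min = 0)
  check_number(wtp_per_qaly, "wtp_per_qaly", min = 0)
  check_number(gdp_per_capita, "gdp_per_capita", min = 0, strict_min = TRUE)
  init <- initial_distribution[STATES]
  if (anyNA(init))
    stop_domain("initial_distribution must be named over %s",
                paste(STATES, collapse = "/"))
  if (abs(sum(init) - 1) > 1e-9 || any(init < 0))
    stop_domain("initial_distribution must be non-negative and sum to 1")
  structure(list(cycle_days = cycle_days, horizon_years = horizon_years,
                 annual_discount_rate = annual_discount_rate,
                 wtp_per_qaly = wtp_per_qaly, gdp_per_capita = gdp_per_capita,
                 initial_distribution = init,
                 half_cycle_correction = half_cycle_correction,
                 rounding_mode = rounding_mode),
            class = "model_settings")
}

#' Number of model cycles implied by the settings
#'
#' `floor(horizon_years * 365.25 / cycle_days)`; 86 cycles for the default
#' 5-year horizon with 21-day cycles.
#'
#' @param settings A [model_settings()].
#' @return Integer cycle count.
#' @export
n_cycles <- function(settings) {
  as.integer(floor(settings$horizon_years * 365.25 / settings$cycle_days))
}

#' A complete two-arm scenario
#'
#' @param name Scenario label.
#' @param strategies List of exactly two [strategy_inputs()]; the first is
#'   the intervention whose incremental results are reported against the
#'   second.
#' @param settings A [model_settings()].
#' @param shared_ranges Named list of `c(low, high)` sensitivity ranges for
#'   parameters shared by both arms (`u_*`, `price_*`, `cost_*`,
#'   `discount_rate`).
#' @return An object of class `ce_scenario`.
#' @export
ce_scenario <- function(name, strategies, settings, shared_ranges = list()) {
  stopifnot(inherits(settings, "model_settings"))
  if (length(strategies) != 2L ||
      !all(vapply(strategies, inherits, TRUE, "strategy_inputs")))
    stop_domain("a scenario needs exactly two strategy_inputs objects")
  ids <- vapply(strategies, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_domain("strategy ids must be distinct")
  names(strategies) <- ids
  sc <- structure(list(name = name, strategies = strategies,
                       settings = settings, shared_ranges = shared_ranges),
                  class = "ce_scenario")
  validate_scenario(sc)
  sc
}

#' Validate a scenario's invariants
#'
#' Checks every sensitivity range contains its base value, that derived
#' transition rows are stochastic, and that the structural invariants of all
#' component objects hold. Called by [ce_scenario()] and [load_config()].
#'
#' @param scenario A `ce_scenario`.
#' @return The scenario, invisibly; errors name the offending field.
#' @export
validate_scenario <- function(scenario) {
  tab <- parameter_table(scenario)
  bad <- tab$base < tab$low - 1e-9 | tab$base > tab$high + 1e-9
  if (any(bad))
    stop_domain("sensitivity range for '%s' does not contain its base value %g",
                tab$param[which(bad)[1]], tab$base[which(bad)[1]])
  for (st in scenario$strategies) {
    pr <- derive_transition_probs(st$clinical,
                                  rounding_mode = scenario$settings$rounding_mode,
                                  overrides = st$prob_overrides)
    assemble_matrix(pr)  # errors if any row is non-stochastic
  }
  invisible(scenario)
}

## ---- published fixtures ---------------------------------------------------

fixture_shared_costs <- function() {
  list(
    ae_costs = c(diarrhea = 4083.63, ppe_syndrome = 2316,
                 vomiting = 945.63, fatigue = 1158.04, anemia = 7350.98),
    other_costs = c(hospitalization = 3200, concomitant_medications = 2176,
                    health_examinations = 4552),
    prices = c(neratinib = 13.46, lapatinib = 16.12, capecitabine = 0.6,
               loperamide = 0.23))
}

fixture_ae_profile <- function(incidences) {
  sh <- fixture_shared_costs()
  data.frame(event = names(sh$ae_costs),
             incidence = as.numeric(incidences[names(sh$ae_costs)]),
             cost_per_event = as.numeric(sh$ae_costs))
}

fixture_loperamide <- function() {
  list(unit_mg = 2, unit_price_usd = 0.23, initial_mg = 4,
       loading_interval_h = 4, loading_days = 3, maintenance_interval_h = 6)
}

fixture_dosing_nc <- function() {
  data.frame(
    drug = c("neratinib", "capecitabine"),
    dose_mg = c(240, 1500), per_m2 = c(FALSE, TRUE),
    unit_mg = c(40, 150), unit_price_usd = c(13.46, 0.6),
    admin_per_day = c(1, 2), days_per_cycle = c(21, 14))
}

fixture_dosing_lc <- function() {
  data.frame(
    drug = c("lapatinib", "capecitabine"),
    dose_mg = c(1250, 2000), per_m2 = c(FALSE, TRUE),
    unit_mg = c(250, 150), unit_price_usd = c(16.12, 0.6),
    admin_per_day = c(1, 2), days_per_cycle = c(21, 14))
}

fixture_shared_ranges <- function() {
  list(
    u_stable = c(0.592, 0.888),     # published low 0.0592 corrected: see vignette
    u_remission = c(0.680, 1.000),
    u_relapse = c(0.400, 0.600),
    price_neratinib = c(12.114, 14.806),
    price_lapatinib = c(14.508, 17.732),
    price_capecitabine = c(0.540, 0.660),
    price_loperamide = c(0.207, 0.253),
    cost_ae_diarrhea = c(3675.267, 4491.993),
    cost_ae_ppe_syndrome = c(2084.400, 2547.600),
    cost_ae_vomiting = c(851.067, 1040.193),
    cost_ae_fatigue = c(1042.236, 1273.844),
    cost_ae_anemia = c(6615.882, 8086.078),
    cost_hospitalization = c(2880.000, 3520.000),
    cost_concomitant_medications = c(1958.400, 2393.600),
    cost_health_examinations = c(4096.800, 5007.200),
    discount_rate = c(0.027, 0.033))
}

pct_range <- function(x, frac = 0.10, clamp01 = FALSE) {
  r <- c(x * (1 - frac), x * (1 + frac))
  if (clamp01) r <- pmin(pmax(r, 0), 1)
  r
}

#' Auto-generate per-arm sensitivity ranges
#'
#' Transition probabilities and adverse-event incidences get +/-10% ranges,
#' clamped to \[0, 1\] — the convention visible in the published ranges (e.g.
#' 0.941 giving 0.8469–1.0000).
#'
#' @param strategy A [strategy_inputs()] (its `sa_ranges` are replaced).
#' @param frac Half-width as a fraction of the base value; default 0.10.
#' @return The strategy with `sa_ranges` filled.
#' @export
auto_sa_ranges <- function(strategy, frac = 0.10) {
  pr <- derive_transition_probs(strategy$clinical)
  full <- c(pr, list(p_ss = 1 - pr$p_sr - pr$p_sp,
                     p_rr = 1 - pr$p_rp, p_pp = 1 - pr$p_pd))
  rng <- lapply(full, pct_range, frac = frac, clamp01 = TRUE)
  inc <- strategy$costs$ae_profile
  for (i in seq_len(nrow(inc)))
    rng[[paste0("inc_", inc$event[i])]] <-
      pct_range(inc$incidence[i], frac, clamp01 = TRUE)
  strategy$sa_ranges <- rng[order(names(rng))]
  strategy
}

#' Published parameter sets for the two study scenarios
#'
#' Returns the complete two-arm scenario exactly as published: clinical
#' summaries, transition-probability sensitivity ranges, utilities, unit drug
#' prices and dosing schedules, adverse-event incidence/cost profiles, other
#' recurring costs, and the global settings (21-day cycles, 5-year horizon,
#' 3% discount, $36,000/QALY threshold).
#'
#' `"whole_group"` is the full trial population (N+C: RR 0.63, OS 24, PFS
#' 8.8, DoR 8.5 months; L+C: RR 0.7, OS 22, PFS 6.6, DoR 5.6).
#' `"asian_subgroup"` uses the Asian-subgroup medians (N+C: OS 23.8, PFS 7.0,
#' DoR 11.1; L+C: OS 18.7, PFS 5.4, DoR 4.2) with risk fractions derived via
#' [derive_rr()] and auto-generated +/-10% probability ranges, costs and
#' utilities unchanged.
#'
#' @param scenario `"whole_group"` or `"asian_subgroup"`.
#' @return A [ce_scenario()].
#' @examples
#' sc <- paper_fixture("whole_group")
#' sc$strategies$nc$clinical$rr  # 0.63
#' @export
paper_fixture <- function(scenario = c("whole_group", "asian_subgroup")) {
  scenario <- match.arg(scenario)
  sh <- fixture_shared_costs()
  utils <- utility_set(stable = 0.74, remission = 0.85, relapse = 0.5,
                       extras = list(u_no_recurrence_post_chemo = 0.94,
                                     u_local_recurrence_year1 = 0.74))
  inc_nc <- c(diarrhea = 0.307, ppe_syndrome = 0.120, vomiting = 0.050,
              fatigue = 0.037, anemia = 0.024)
  inc_lc <- c(diarrhea = 0.143, ppe_syndrome = 0.138, vomiting = 0.024,
              fatigue = 0.040, anemia = 0.044)
  costs_nc <- cost_schedule(fixture_dosing_nc(), fixture_ae_profile(inc_nc),
                            sh$other_costs, loperamide = fixture_loperamide())
  costs_lc <- cost_schedule(fixture_dosing_lc(), fixture_ae_profile(inc_lc),
                            sh$other_costs)

  if (scenario == "whole_group") {
    cl_nc <- clinical_summary(os_months = 24, pfs_months = 8.8,
                              dor_months = 8.5, rr = 0.63)
    cl_lc <- clinical_summary(os_months = 22, pfs_months = 6.6,
                              dor_months = 5.6, rr = 0.7)
    rng_nc <- list(p_ss = c(0.5175, 0.6325), p_sr = c(0.1701, 0.2079),
                   p_sp = c(0.2124, 0.2596), p_rr = c(0.8469, 1.0000),
                   p_rp = c(0.0531, 0.0649), p_pp = c(0.8694, 1.0000),
                   p_pd = c(0.0306, 0.0374))
    rng_lc <- list(p_ss = c(0.3960, 0.4840), p_sr = c(0.1872, 0.2288),
                   p_sp = c(0.3168, 0.3872), p_rr = c(0.8208, 1.0000),
                   p_rp = c(0.0792, 0.0968), p_pp = c(0.8703, 1.0000),
                   p_pd = c(0.0297, 0.0363))
    for (ev in names(inc_nc)) {
      rng_nc[[paste0("inc_", ev)]] <- pct_range(inc_nc[[ev]], clamp01 = TRUE)
      rng_lc[[paste0("inc_", ev)]] <- pct_range(inc_lc[[ev]], clamp01 = TRUE)
    }
    nc <- strategy_inputs("nc", "N+C", cl_nc, costs_nc, utils, rng_nc)
    lc <- strategy_inputs("lc", "L+C", cl_lc, costs_lc, utils, rng_lc)
  } else {
    cl_nc <- clinical_summary(os_months = 23.8, pfs_months = 7.0,
                              dor_months = 11.1)
    cl_lc <- clinical_summary(os_months = 18.7, pfs_months = 5.4,
                              dor_months = 4.2)
    nc <- auto_sa_ranges(strategy_inputs("nc", "N+C", cl_nc, costs_nc, utils))
    lc <- auto_sa_ranges(strategy_inputs("lc", "L+C", cl_lc, costs_lc, utils))
  }
  ce_scenario(name = scenario, strategies = list(nc, lc),
              settings = model_settings(),
              shared_ranges = fixture_shared_ranges())
}

## ---- sensitivity parameter table ------------------------------------------

#' Enumerate every varied parameter of a scenario
#'
#' Builds the master table used by [one_way_dsa()] and [run_psa()]: one row
#' per parameter with its base value, sensitivity range, distribution family
#' (beta for probabilities/utilities/incidences, gamma for costs) and role.
#' Arm-level parameters are prefixed with the strategy id
#' (`"nc.p_rp"`); utilities, unit prices, other costs and the discount rate
#' are shared between arms and varied jointly. Self-transition complements
#' (`p_ss`, `p_rr`, `p_pp`) are marked `complement = TRUE`: varying them
#' adjusts their constituent probabilities (see [apply_parameter()]) and they
#' are excluded from probabilistic sampling.
#'
#' @param scenario A `ce_scenario`.
#' @return Data frame with columns `param`, `base`, `low`, `high`, `dist`,
#'   `complement`.
#' @export
parameter_table <- function(scenario) {
  rows <- list()
  add <- function(param, base, range, dist, complement = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      param = param, base = base, low = range[1], high = range[2],
      dist = dist, complement = complement)
  }
  for (st in scenario$strategies) {
    pr <- derive_transition_probs(st$clinical, overrides = st$prob_overrides)
    full <- c(pr, list(p_ss = 1 - pr$p_sr - pr$p_sp,
                       p_rr = 1 - pr$p_rp, p_pp = 1 - pr$p_pd))
    for (nm in names(st$sa_ranges)) {
      rng <- st$sa_ranges[[nm]]
      if (startsWith(nm, "p_")) {
        add(paste0(st$id, ".", nm), full[[nm]], rng, "beta",
            complement = nm %in% c("p_ss", "p_rr", "p_pp"))
      } else if (startsWith(nm, "inc_")) {
        ev <- sub("^inc_", "", nm)
        base <- st$costs$ae_profile$incidence[st$costs$ae_profile$event == ev]
        add(paste0(st$id, ".", nm), base, rng, "beta")
      }
    }
  }
  st1 <- scenario$strategies[[1]]
  for (nm in names(scenario$shared_ranges)) {
    rng <- scenario$shared_ranges[[nm]]
    if (startsWith(nm, "u_")) {
      base <- st1$utilities[[sub("^u_", "", nm)]]
      add(nm, base, rng, "beta")
    } else if (startsWith(nm, "price_")) {
      base <- shared_price(scenario, sub("^price_", "", nm))
      add(nm, base, rng, "gamma")
    } else if (startsWith(nm, "cost_ae_")) {
      ev <- sub("^cost_ae_", "", nm)
      base <- NA_real_
      for (st in scenario$strategies) {
        hit <- st$costs$ae_profile$cost_per_event[st$costs$ae_profile$event == ev]
        if (length(hit)) base <- hit[1]
      }
      add(nm, base, rng, "gamma")
    } else if (startsWith(nm, "cost_")) {
      base <- st1$costs$other_costs[[sub("^cost_", "", nm)]]
      add(nm, base, rng, "gamma")
    } else if (nm == "discount_rate") {
      add(nm, scenario$settings$annual_discount_rate, rng, "beta")
    } else {
      stop_domain("unrecognized shared parameter '%s'", nm)
    }
  }
  do.call(rbind, rows)
}

shared_price <- function(scenario, drug) {
  for (st in scenario$strategies) {
    d <- st$costs$dosing
    if (drug %in% d$drug) return(d$unit_price_usd[d$drug == drug][1])
    lp <- st$costs$loperamide
    if (drug == "loperamide" && !is.null(lp)) return(lp$unit_price_usd)
  }
  stop_domain("no strategy uses drug '%s'", drug)
}

#' Set one named parameter in a scenario
#'
#' Returns a modified copy of the scenario with the parameter at `value`.
#' Transition probabilities are set as overrides on the derived per-cycle
#' probabilities; the same-row self-transition complement absorbs the change
#' so rows stay stochastic. Setting a complement (`p_ss`, `p_rr`, `p_pp`) is
#' mapped to its constituents: `p_rr` and `p_pp` set `p_rp = 1 - value` and
#' `p_pd = 1 - value`; `p_ss` rescales `p_sr` and `p_sp` proportionally so
#' they sum to `1 - value`. Shared parameters (utilities, prices, costs) are
#' applied to both arms.
#'
#' @param scenario A `ce_scenario`.
#' @param param Parameter name as listed by [parameter_table()].
#' @param value New value.
#' @return The modified scenario.
#' @export
apply_parameter <- function(scenario, param, value) {
  if (param == "discount_rate") {
    check_number(value, param, min = 0)
    scenario$settings$annual_discount_rate <- value
    return(scenario)
  }
  if (grepl("^u_", param)) {
    check_number(value, param, 0, 1)
    slot <- sub("^u_", "", param)
    for (id in names(scenario$strategies)) {
      if (is.null(scenario$strategies[[id]]$utilities[[slot]]))
        stop_domain("unknown utility '%s'", param)
      scenario$strategies[[id]]$utilities[[slot]] <- value
    }
    return(scenario)
  }
  if (grepl("^price_", param)) {
    check_number(value, param, min = 0)
    drug <- sub("^price_", "", param)
    for (id in names(scenario$strategies)) {
      d <- scenario$strategies[[id]]$costs$dosing
      d$unit_price_usd[d$drug == drug] <- value
      scenario$strategies[[id]]$costs$dosing <- d
      lp <- scenario$strategies[[id]]$costs$loperamide
      if (drug == "loperamide" && !is.null(lp)) {
        lp$unit_price_usd <- value
        scenario$strategies[[id]]$costs$loperamide <- lp
      }
    }
    return(scenario)
  }
  if (grepl("^cost_ae_", param)) {
    check_number(value, param, min = 0)
    ev <- sub("^cost_ae_", "", param)
    for (id in names(scenario$strategies)) {
      a <- scenario$strategies[[id]]$costs$ae_profile
      a$cost_per_event[a$event == ev] <- value
      scenario$strategies[[id]]$costs$ae_profile <- a
    }
    return(scenario)
  }
  if (grepl("^cost_", param)) {
    check_number(value, param, min = 0)
    slot <- sub("^cost_", "", param)
    for (id in names(scenario$strategies)) {
      oc <- scenario$strategies[[id]]$costs$other_costs
      if (!slot %in% names(oc)) stop_domain("unknown cost component '%s'", param)
      oc[[slot]] <- value
      scenario$strategies[[id]]$costs$other_costs <- oc
    }
    return(scenario)
  }
  # arm-scoped: "<id>.p_xx" or "<id>.inc_<event>"
  m <- regmatches(param, regexec("^([a-z][a-z0-9_]*)\\.(.+)$", param))[[1]]
  if (length(m) != 3L || !m[2] %in% names(scenario$strategies))
    stop_domain("unrecognized parameter '%s'", param)
  id <- m[2]; sub <- m[3]
  st <- scenario$strategies[[id]]
  if (grepl("^inc_", sub)) {
    check_number(value, param, 0, 1)
    ev <- sub("^inc_", "", sub)
    a <- st$costs$ae_profile
    if (!ev %in% a$event) stop_domain("unknown adverse event '%s'", param)
    a$incidence[a$event == ev] <- value
    st$costs$ae_profile <- a
  } else if (grepl("^p_", sub)) {
    check_number(value, param, 0, 1)
    pr <- derive_transition_probs(st$clinical, overrides = st$prob_overrides)
    ov <- as.list(st$prob_overrides %||% numeric())
    if (sub %in% c("p_sr", "p_sp", "p_rp", "p_pd")) {
      ov[[sub]] <- value
    } else if (sub == "p_rr") {
      ov[["p_rp"]] <- 1 - value
    } else if (sub == "p_pp") {
      ov[["p_pd"]] <- 1 - value
    } else if (sub == "p_ss") {
      denom <- pr$p_sr + pr$p_sp
      if (denom <= 0) stop_domain("cannot rescale '%s': zero exit probability", param)
      scl <- (1 - value) / denom
      ov[["p_sr"]] <- pr$p_sr * scl
      ov[["p_sp"]] <- pr$p_sp * scl
    } else {
      stop_domain("unrecognized transition parameter '%s'", param)
    }
    st$prob_overrides <- unlist(ov)
  } else {
    stop_domain("unrecognized parameter '%s'", param)
  }
  scenario$strategies[[id]] <- st
  scenario
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- config I/O ------------------------------------------------------------

strategy_to_list <- function(st) {
  list(id = st$id, name = st$name,
       clinical = unclass(st$clinical),
       utilities = unclass(st$utilities),
       costs = list(
         dosing = lapply(seq_len(nrow(st$costs$dosing)),
                         function(i) as.list(st$costs$dosing[i, ])),
         ae_profile = lapply(seq_len(nrow(st$costs$ae_profile)),
                             function(i) as.list(st$costs$ae_profile[i, ])),
         other_costs = as.list(st$costs$other_costs),
         bsa_m2 = st$costs$bsa_m2,
         loperamide = st$costs$loperamide,
         other_cost_period = st$costs$other_cost_period,
         drug_states = st$costs$drug_states),
       sa_ranges = lapply(st$sa_ranges, as.numeric))
}

strategy_from_list <- function(x) {
  cl <- clinical_summary(os_months = x$clinical$os_months,
                         pfs_months = x$clinical$pfs_months,
                         dor_months = x$clinical$dor_months,
                         rr = x$clinical$rr)
  ut <- utility_set(stable = x$utilities$stable,
                    remission = x$utilities$remission,
                    relapse = x$utilities$relapse,
                    extras = x$utilities$extras %||% list())
  cs <- cost_schedule(
    dosing = do.call(rbind, lapply(x$costs$dosing, as.data.frame)),
    ae_profile = do.call(rbind, lapply(x$costs$ae_profile, as.data.frame)),
    other_costs = unlist(x$costs$other_costs),
    bsa_m2 = x$costs$bsa_m2,
    loperamide = x$costs$loperamide,
    other_cost_period = x$costs$other_cost_period,
    drug_states = unlist(x$costs$drug_states))
  strategy_inputs(x$id, x$name, cl, cs, ut,
                  sa_ranges = lapply(x$sa_ranges, as.numeric))
}

#' Write a scenario to a YAML config file
#'
#' The file is a complete, human-editable description of the model inputs;
#' [load_config()] restores an identical scenario (round-trip identity on all
#' fields, numeric values to full precision).
#'
#' @param scenario A `ce_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(scenario, path) {
  out <- list(
    schema = "mbcmarkov-scenario/1",
    name = scenario$name,
    settings = lapply(unclass(scenario$settings), function(v)
      if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
    strategies = lapply(unname(scenario$strategies), strategy_to_list),
    shared_ranges = lapply(scenario$shared_ranges, as.numeric))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read and validate a scenario config file
#'
#' @param path Path to a YAML file written by [save_config()] (schema
#'   `mbcmarkov-scenario/1`), e.g. the shipped files under
#'   `system.file("extdata", package = "mbcmarkov")`.
#' @return A validated [ce_scenario()]. Schema violations and domain errors
#'   (such as OS <= PFS) fail with a message naming the field.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_domain("config file '%s' does not exist", path)
  x <- yaml::read_yaml(path)
  if (!identical(x$schema, "mbcmarkov-scenario/1"))
    stop_domain("unrecognized config schema '%s'", x$schema %||% "<missing>")
  s <- x$settings
  settings <- model_settings(
    cycle_days = s$cycle_days, horizon_years = s$horizon_years,
    annual_discount_rate = s$annual_discount_rate,
    wtp_per_qaly = s$wtp_per_qaly, gdp_per_capita = s$gdp_per_capita,
    initial_distribution = unlist(s$initial_distribution),
    half_cycle_correction = s$half_cycle_correction,
    rounding_mode = s$rounding_mode)
  ce_scenario(name = x$name,
              strategies = lapply(x$strategies, strategy_from_list),
              settings = settings,
              shared_ranges = lapply(x$shared_ranges, as.numeric))
}

#' Export the scenario's parameters as a flat CSV table
#'
#' One row per varied parameter (see [parameter_table()]) with base value,
#' range and distribution family — the layout of a published key-parameters
#' table.
#'
#' @param scenario A `ce_scenario`.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
export_parameter_csv <- function(scenario, path) {
  tab <- parameter_table(scenario)
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
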