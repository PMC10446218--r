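# Independent oracles and small builders shared across the suite.
# These deliberately avoid the package's cohort engine: occupancy comes from
# explicit matrix powers and accruals from directly summed series, so the
# engine is checked against a second, structurally different computation.

# random row-stochastic 4x4 matrix (Dirichlet rows via normalized gammas)
random_stochastic_matrix <- function() {
  m <- matrix(rgamma(16, shape = 1), 4, 4)
  m <- m / rowSums(m)
  dimnames(m) <- list(mbcmarkov::STATES, mbcmarkov::STATES)
  m
}

matrix_power <- function(m, k) {
  out <- diag(nrow(m))
  for (i in seq_len(k)) out <- out %*% m
  out
}

# totals by direct summation of the matrix-power series
oracle_totals <- function(m, init, state_cost, state_utility, one_time,
                          n, rate, cycle_days, convention) {
  w <- switch(convention,
              half_cycle = c(0.5, rep(1, n - 1), 0.5),
              start = c(rep(1, n), 0),
              end = c(0, rep(1, n)))
  cost <- one_time
  qaly <- 0
  for (t in 0:n) {
    occ <- as.numeric(init %*% matrix_power(m, t))
    d <- (1 + rate)^(-t * cycle_days / 365.25)
    cost <- cost + w[t + 1] * d * sum(occ * state_cost)
    qaly <- qaly + w[t + 1] * d * sum(occ * state_utility) *
      cycle_days / 365.25
  }
  list(total_cost = cost, total_qaly = qaly)
}

# settings with a short horizon for oracle comparisons
short_settings <- function(n_cyc, rate = 0.03, hcc = TRUE) {
  mbcmarkov::model_settings(
    cycle_days = 21,
    horizon_years = (n_cyc * 21 + 1) / 365.25,
    annual_discount_rate = rate,
    half_cycle_correction = hcc)
}

# zero-width copy of every sensitivity range: the PSA collapses to the base
degenerate_scenario <- function(sc) {
  tab <- mbcmarkov::parameter_table(sc)
  for (id in names(sc$strategies)) {
    rngs <- sc$strategies[[id]]$sa_ranges
    for (nm in names(rngs)) {
      base <- tab$base[tab$param == paste0(id, ".", nm)]
      rngs[[nm]] <- c(base, base)
    }
    sc$strategies[[id]]$sa_ranges <- rngs
  }
  for (nm in names(sc$shared_ranges)) {
    base <- tab$base[tab$param == nm]
    sc$shared_ranges[[nm]] <- c(base, base)
  }
  sc
}

random_valid_clinical <- function() {
  os <- runif(1, 10, 60)
  pfs <- os * runif(1, 0.2, 0.8)
  dor <- max(2.7, pfs * runif(1, 0.5, 2))
  mbcmarkov::clinical_summary(os_months = os, pfs_months = pfs,
                              dor_months = dor)
}
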