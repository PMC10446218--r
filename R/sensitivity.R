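## One-way deterministic sensitivity analysis (tornado), second-order
## Monte-Carlo probabilistic sensitivity analysis, and acceptability curves.

#' Fit a beta or gamma distribution from a base value and range
#'
#' Method-of-moments fit with mean equal to the base value and standard
#' deviation `(high - low) / (2 * 1.96)` — the sensitivity range read as a
#' 95% interval. Beta for quantities on \[0, 1\] (probabilities, utilities,
#' incidences), gamma for costs. A zero-width range yields a point mass.
#'
#' @param base Base value (the distribution mean).
#' @param range_low,range_high Sensitivity range, `range_low <= base <=
#'   range_high`.
#' @param family `"beta"` or `"gamma"`.
#' @return A `param_dist`: list with `family`, `mean`, `sd` and the fitted
#'   shape parameters (`shape1`/`shape2` or `shape`/`scale`).
#' @examples
#' fit_distribution(0.189, 0.1701, 0.2079, "beta")$sd    # 0.009643
#' fit_distribution(13.46, 12.114, 14.806, "gamma")$sd   # 0.6867
#' @export
fit_distribution <- function(base, range_low, range_high,
                             family = c("beta", "gamma")) {
  family <- match.arg(family)
  if (range_low > base + 1e-12 || range_high < base - 1e-12)
    stop_domain("range [%g, %g] does not contain the base value %g",
                range_low, range_high, base)
  s <- (range_high - range_low) / (2 * 1.96)
  out <- list(family = family, mean = base, sd = s)
  if (s == 0) {
    out$degenerate <- TRUE
    class(out) <- "param_dist"
    return(out)
  }
  out$degenerate <- FALSE
  v <- s^2
  if (family == "beta") {
    if (base <= 0 || base >= 1)
      stop_domain("beta fit needs a mean strictly inside (0, 1); got %g", base)
    if (v >= base * (1 - base))
      stop_domain(paste0(
        "beta fit impossible: variance %g >= mean*(1-mean) = %g; ",
        "narrow the sensitivity range or use a gamma family"),
        v, base * (1 - base))
    k <- base * (1 - base) / v - 1
    out$shape1 <- base * k
    out$shape2 <- (1 - base) * k
  } else {
    if (base <= 0)
      stop_domain("gamma fit needs a positive mean; got %g", base)
    out$shape <- base^2 / v
    out$scale <- v / base
  }
  class(out) <- "param_dist"
  out
}

#' Draw from a fitted parameter distribution
#'
#' @param dist A `param_dist` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n` (all equal to the mean for a point
#'   mass).
#' @export
draw_distribution <- function(dist, n) {
  if (dist$degenerate) return(rep(dist$mean, n))
  if (dist$family == "beta") rbeta(n, dist$shape1, dist$shape2)
  else rgamma(n, shape = dist$shape, scale = dist$scale)
}

scenario_icer <- function(scenario) {
  compare_strategies(scenario)$icer$icer
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full pipeline with each parameter at its low and at its high
#' bound, all others at base, and records the ICER swing. Rows are sorted by
#' bar width (`|icer_high - icer_low|`), widest first — the tornado order.
#' A parameter setting that cannot produce a valid model (e.g. a probability
#' variation that breaks row-stochasticity) flags the row instead of
#' aborting the analysis.
#'
#' @param scenario A [ce_scenario()].
#' @param params Optional character vector restricting the analysis to a
#'   subset of [parameter_table()] rows.
#' @return Data frame (class `dsa_result`) with columns `param`, `base`,
#'   `low`, `high`, `icer_low`, `icer_high`, `bar_width`, `flagged`;
#'   attribute `base_icer` carries the base-case ICER.
#' @export
one_way_dsa <- function(scenario, params = NULL) {
  tab <- parameter_table(scenario)
  if (!is.null(params)) {
    miss <- setdiff(params, tab$param)
    if (length(miss))
      stop_domain("unknown parameter(s): %s", paste(miss, collapse = ", "))
    tab <- tab[tab$param %in% params, ]
  }
  base_icer <- scenario_icer(scenario)
  eval_at <- function(param, value) {
    tryCatch(scenario_icer(apply_parameter(scenario, param, value)),
             error = function(e) NA_real_)
  }
  icer_low <- mapply(eval_at, tab$param, tab$low)
  icer_high <- mapply(eval_at, tab$param, tab$high)
  out <- data.frame(param = tab$param, base = tab$base, low = tab$low,
                    high = tab$high, icer_low = icer_low,
                    icer_high = icer_high,
                    bar_width = abs(icer_high - icer_low),
                    flagged = is.na(icer_low) | is.na(icer_high))
  out <- out[order(-out$bar_width, out$param), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  class(out) <- c("dsa_result", class(out))
  out
}

#' Second-order Monte-Carlo probabilistic sensitivity analysis
#'
#' Per draw, every sampled parameter is drawn independently from its fitted
#' beta/gamma distribution (see [fit_distribution()]; transition
#' probabilities are the derived per-cycle values, with self-transition
#' complements absorbing the change), both arms are re-run, and the
#' incremental cost and QALYs are recorded. Complement parameters and the
#' discount rate are held fixed. Draws whose sampled stable-disease exits
#' exceed 1 are resampled and counted; more than 1% invalid aborts with a
#' diagnostic. Fully reproducible for a given seed.
#'
#' @param scenario A [ce_scenario()].
#' @param n_draws Number of Monte-Carlo draws (default 1000).
#' @param seed Integer RNG seed (required).
#' @param wtp Willingness-to-pay for quadrant/NMB summaries; default from
#'   the settings.
#' @return A `psa_result`: list with `draws` (data frame: per-arm cost and
#'   QALYs, increments, NMBs), `quadrants` (fractions over
#'   `dominant` / `ce_below_wtp` / `above_wtp_favourable` /
#'   `comparator_favoured` / `indifferent`), `n_draws`, `n_invalid`, `seed`,
#'   `wtp`.
#' @export
run_psa <- function(scenario, n_draws = 1000, seed, wtp = NULL) {
  if (missing(seed)) stop_domain("run_psa requires an explicit seed")
  check_number(n_draws, "n_draws", min = 1)
  wtp <- wtp %||% scenario$settings$wtp_per_qaly
  tab <- parameter_table(scenario)
  tab <- tab[!tab$complement & tab$param != "discount_rate", ]
  dists <- lapply(seq_len(nrow(tab)), function(i)
    fit_distribution(tab$base[i], tab$low[i], tab$high[i], tab$dist[i]))
  names(dists) <- tab$param

  set.seed(as.integer(seed))
  rows <- vector("list", n_draws)
  n_invalid <- 0L
  for (i in seq_len(n_draws)) {
    repeat {
      vals <- vapply(dists, draw_distribution, 0, n = 1L)
      sc <- scenario
      for (j in seq_along(vals))
        sc <- apply_parameter(sc, names(vals)[j], vals[[j]])
      ok <- tryCatch({
        res <- compare_strategies(sc, wtp = wtp)
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      n_invalid <- n_invalid + 1L
      if (n_invalid > max(10, 0.01 * n_draws))
        stop_domain(paste0(
          "more than 1%% of PSA draws produced invalid transition rows ",
          "(%d invalid); check the sensitivity ranges"), n_invalid)
    }
    s <- res$strategies
    rows[[i]] <- c(cost_a = s$total_cost[1], qaly_a = s$total_qaly[1],
                   cost_b = s$total_cost[2], qaly_b = s$total_qaly[2])
  }
  draws <- as.data.frame(do.call(rbind, rows))
  draws$draw <- seq_len(n_draws)
  draws$delta_cost <- draws$cost_a - draws$cost_b
  draws$delta_qaly <- draws$qaly_a - draws$qaly_b
  draws$nmb_a <- compute_nmb(draws$cost_a, draws$qaly_a, wtp)
  draws$nmb_b <- compute_nmb(draws$cost_b, draws$qaly_b, wtp)

  structure(list(draws = draws,
                 quadrants = psa_quadrants(draws, wtp),
                 n_draws = n_draws, n_invalid = n_invalid,
                 seed = as.integer(seed), wtp = wtp,
                 names = vapply(scenario$strategies, `[[`, "", "name")),
            class = "psa_result")
}

psa_quadrants <- function(draws, wtp) {
  dc <- draws$delta_cost; dq <- draws$delta_qaly
  indiff <- dq == 0 & dc == 0
  dominant <- dq > 0 & dc < 0
  below <- dq > 0 & dc >= 0 & !indiff & (dc / dq) < wtp
  above <- dq > 0 & dc >= 0 & (dc / dq) >= wtp
  comp <- !(indiff | dominant | below | above)
  c(dominant = mean(dominant), ce_below_wtp = mean(below),
    above_wtp_favourable = mean(above), comparator_favoured = mean(comp),
    indifferent = mean(indiff))
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d, %d resampled), WTP %.0f USD/QALY\n",
              x$n_draws, x$seed, x$n_invalid, x$wtp))
  q <- round(100 * x$quadrants, 1)
  cat(sprintf("  %s dominant: %.1f%%; costlier but below WTP: %.1f%%; above WTP: %.1f%%\n",
              x$names[1], q["dominant"], q["ce_below_wtp"],
              q["above_wtp_favourable"]))
  cat(sprintf("  favouring %s: %.1f%%; indifferent: %.1f%%\n",
              x$names[2], q["comparator_favoured"], q["indifferent"]))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that each strategy has
#' the strictly greater net monetary benefit across the PSA draws; exact
#' NMB ties are split evenly. The two curves sum to 1 pointwise.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Numeric grid of WTP values; default 0 to 64,000 by 1,000.
#' @return Data frame with `wtp`, `prob_a`, `prob_b`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 64000, by = 1000)) {
  if (!length(wtp_grid)) stop_domain("wtp_grid must be non-empty")
  d <- psa$draws
  prob_a <- vapply(wtp_grid, function(w) {
    na <- compute_nmb(d$cost_a, d$qaly_a, w)
    nb <- compute_nmb(d$cost_b, d$qaly_b, w)
    mean(na > nb) + 0.5 * mean(na == nb)
  }, 0)
  data.frame(wtp = wtp_grid, prob_a = prob_a, prob_b = 1 - prob_a)
}
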