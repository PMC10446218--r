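## Pairwise cost-effectiveness arithmetic: increments, ICER, NMB, dominance
## and the GDP-tier decision rule.

#' Incremental cost-effectiveness ratio of strategy A versus B
#'
#' Increments are `A - B`. When the QALY increment is nonzero the ICER is
#' `delta_cost / delta_qaly`, reported with its sign (a negative ratio is
#' ambiguous on its own, so the cost-effectiveness-plane quadrant is always
#' attached). Degenerate increments are tagged, never thrown.
#'
#' @param cost_a,cost_b Total discounted costs, USD.
#' @param qaly_a,qaly_b Total discounted QALYs.
#' @return List with `delta_cost`, `delta_qaly`, `icer` (`NA` when
#'   undefined) and `quadrant`: one of `"dominant"` (A cheaper, more
#'   effective), `"dominated"`, `"ne"` (A costlier, more effective), `"sw"`
#'   (A cheaper, less effective), `"equal_effect"`, `"indifferent"`.
#' @examples
#' compute_icer(30742.90, 31305.98, 2.49, 2.26)  # icer = -2448.17...
#' @export
compute_icer <- function(cost_a, cost_b, qaly_a, qaly_b) {
  stopifnot(is.finite(cost_a), is.finite(cost_b),
            is.finite(qaly_a), is.finite(qaly_b))
  dc <- cost_a - cost_b
  dq <- qaly_a - qaly_b
  quadrant <-
    if (dq == 0 && dc == 0) "indifferent"
    else if (dq == 0) "equal_effect"
    else if (dq > 0 && dc < 0) "dominant"
    else if (dq < 0 && dc > 0) "dominated"
    else if (dq > 0) "ne"
    else "sw"
  icer <- if (dq == 0) NA_real_ else dc / dq
  list(delta_cost = dc, delta_qaly = dq, icer = icer, quadrant = quadrant)
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`: positive when the health gained, valued at the
#' willingness-to-pay threshold, outweighs the cost.
#'
#' @param cost Total cost, USD.
#' @param qaly Total QALYs.
#' @param wtp Willingness to pay, USD per QALY (>= 0).
#' @return NMB in USD.
#' @export
compute_nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop_domain("wtp must be >= 0")
  wtp * qaly - cost
}

#' Decision tier under the GDP-multiple rule
#'
#' Chinese pharmacoeconomic guideline bands: an ICER below one per-capita
#' GDP is cost-effective, between one and three GDPs acceptable, above three
#' not worthwhile. Dominance short-circuits the banding; a dominated
#' strategy is its own tier. In the south-west quadrant (cheaper, less
#' effective) the ICER is savings per QALY forgone, so the bands invert:
#' savings of at least 3x GDP per QALY lost are classed acceptable,
#' smaller savings not worthwhile.
#'
#' @param icer_result Result of [compute_icer()].
#' @param gdp_per_capita Per-capita GDP, USD (> 0).
#' @return One of `"dominant"`, `"cost_effective"`, `"acceptable"`,
#'   `"not_worthwhile"`, `"dominated"`, `"indifferent"`.
#' @export
classify_decision <- function(icer_result, gdp_per_capita) {
  check_number(gdp_per_capita, "gdp_per_capita", min = 0, strict_min = TRUE)
  q <- icer_result$quadrant
  if (q == "dominant") return("dominant")
  if (q == "dominated") return("dominated")
  if (q == "indifferent") return("indifferent")
  if (q == "equal_effect")
    return(if (icer_result$delta_cost <= 0) "cost_effective" else "dominated")
  icer <- icer_result$icer
  if (q == "sw")
    return(if (icer >= 3 * gdp_per_capita) "acceptable" else "not_worthwhile")
  if (icer < gdp_per_capita) "cost_effective"
  else if (icer <= 3 * gdp_per_capita) "acceptable"
  else "not_worthwhile"
}

#' Full cost-effectiveness comparison of a two-arm scenario
#'
#' Runs both strategies through the cohort engine and assembles totals,
#' increments (first strategy minus second), ICER with quadrant, per-strategy
#' NMB at the willingness-to-pay threshold, and the GDP-tier decision.
#'
#' @param scenario A [ce_scenario()].
#' @param wtp Willingness-to-pay threshold; default from the scenario
#'   settings.
#' @return A `ce_result`: list with `strategies` (data frame of per-arm
#'   totals and NMB), `increments`, `icer` (see [compute_icer()]),
#'   `decision`, `wtp`, and the two `cohort_trace` objects in `traces`.
#' @examples
#' \donttest{
#' res <- compare_strategies(paper_fixture("whole_group"))
#' res$increments
#' }
#' @export
compare_strategies <- function(scenario, wtp = NULL) {
  wtp <- wtp %||% scenario$settings$wtp_per_qaly
  traces <- lapply(scenario$strategies, run_strategy,
                   settings = scenario$settings)
  tot <- lapply(traces, `[[`, "totals")
  df <- data.frame(
    id = names(traces),
    name = vapply(scenario$strategies, `[[`, "", "name"),
    total_cost = vapply(tot, `[[`, 0, "total_cost"),
    total_qaly = vapply(tot, `[[`, 0, "total_qaly"),
    death_fraction = vapply(tot, `[[`, 0, "death_fraction"),
    row.names = NULL)
  df$nmb <- compute_nmb(df$total_cost, df$total_qaly, wtp)
  icer <- compute_icer(df$total_cost[1], df$total_cost[2],
                       df$total_qaly[1], df$total_qaly[2])
  structure(list(
    strategies = df,
    increments = c(delta_cost = icer$delta_cost, delta_qaly = icer$delta_qaly),
    icer = icer,
    decision = classify_decision(icer, scenario$settings$gdp_per_capita),
    wtp = wtp,
    traces = traces),
    class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Cost-effectiveness comparison (", x$strategies$name[1], " vs ",
      x$strategies$name[2], ")\n", sep = "")
  print(transform(x$strategies,
                  total_cost = round(total_cost, 2),
                  total_qaly = round(total_qaly, 4),
                  death_fraction = round(death_fraction, 3),
                  nmb = round(nmb, 2)), row.names = FALSE)
  cat(sprintf("  increments: delta cost %.2f USD, delta QALY %.4f\n",
              x$increments["delta_cost"], x$increments["delta_qaly"]))
  if (is.na(x$icer$icer)) {
    cat(sprintf("  ICER: undefined (%s)\n", x$icer$quadrant))
  } else {
    cat(sprintf("  ICER: %.2f USD/QALY (%s quadrant)\n",
                x$icer$icer, x$icer$quadrant))
  }
  cat(sprintf("  decision at WTP %.0f: %s\n", x$wtp, x$decision))
  invisible(x)
}

#' Markdown summary table of a comparison
#'
#' Mirrors the layout of a published cost-and-effect table: per-arm totals,
#' increments, ICER (with quadrant tag) and NMB.
#'
#' @param ce A `ce_result`.
#' @return Character vector of markdown lines.
#' @export
ce_markdown <- function(ce) {
  s <- ce$strategies
  icer_txt <- if (is.na(ce$icer$icer)) ce$icer$quadrant
    else sprintf("%.2f (%s)", ce$icer$icer, ce$icer$quadrant)
  c(sprintf("| Item | %s | %s | Increment |", s$name[1], s$name[2]),
    "|---|---|---|---|",
    sprintf("| Cost (USD) | %.2f | %.2f | %.2f |",
            s$total_cost[1], s$total_cost[2], ce$increments["delta_cost"]),
    sprintf("| QALYs | %.4f | %.4f | %.4f |",
            s$total_qaly[1], s$total_qaly[2], ce$increments["delta_qaly"]),
    sprintf("| Dead at horizon | %.1f%% | %.1f%% | |",
            100 * s$death_fraction[1], 100 * s$death_fraction[2]),
    sprintf("| NMB at %.0f/QALY | %.2f | %.2f | |",
            ce$wtp, s$nmb[1], s$nmb[2]),
    sprintf("| ICER (USD/QALY) | | | %s |", icer_txt),
    sprintf("| Decision | | | %s |", ce$decision))
}

#' Write a ce_result to JSON
#'
#' @param ce A `ce_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_ce_json <- function(ce, path) {
  out <- list(strategies = ce$strategies,
              increments = as.list(ce$increments),
              icer = ce$icer, decision = ce$decision, wtp = ce$wtp)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
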