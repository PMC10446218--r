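## ggplot2 figures: tornado diagram, cost-effectiveness plane, CEAC.

#' Tornado diagram of a one-way sensitivity analysis
#'
#' Horizontal bars spanning the ICER at each parameter's low and high bound,
#' widest at the top, with the base-case ICER as a dashed reference line.
#'
#' @param dsa A `dsa_result` from [one_way_dsa()].
#' @param top Number of widest bars to show (default 15).
#' @return A ggplot object.
#' @export
plot_tornado <- function(dsa, top = 15) {
  d <- dsa[!dsa$flagged, , drop = FALSE]
  d <- utils::head(d, top)
  d$param <- factor(d$param, levels = rev(d$param))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$param)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$param),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(dsa, "base_icer"),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane of PSA draws
#'
#' Incremental QALYs against incremental cost, one point per Monte-Carlo
#' draw, with the willingness-to-pay threshold as a line through the origin.
#' Points below the line favour the first strategy at that threshold.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  d <- psa$draws
  d$favoured <- ifelse(d$nmb_a > d$nmb_b, psa$names[1], psa$names[2])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost,
                                  colour = .data$favoured)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_abline(slope = psa$wtp, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::scale_colour_manual(values = c("forestgreen", "firebrick")) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  colour = "Favoured",
                  title = sprintf("Cost-effectiveness plane (WTP %.0f USD/QALY)",
                                  psa$wtp)) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' Probability that each strategy has the higher net monetary benefit, as a
#' function of the willingness-to-pay threshold.
#'
#' @param ceac_df Data frame from [ceac()].
#' @param names Length-2 strategy labels.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df, names = c("A", "B")) {
  names <- unname(names)
  d <- rbind(
    data.frame(wtp = ceac_df$wtp, prob = ceac_df$prob_a, strategy = names[1]),
    data.frame(wtp = ceac_df$wtp, prob = ceac_df$prob_b, strategy = names[2]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wtp, y = .data$prob,
                                  colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective", colour = NULL,
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
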