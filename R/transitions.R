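## DEALE-style conversion of median survival summaries into per-cycle
## transition probabilities, and assembly of the structural 4x4 matrix.

#' Model constants of the probability derivation
#'
#' `CYCLE_MONTH_FACTOR` (0.75) scales the median-derived hazard
#' `ln(2)/median` to the 21-day cycle; `RR_SCALE` (3) divides the risk
#' fraction in the stable-to-remission formula `1 - exp(-RR/3)`; and
#' `STABLE_RELAPSE_MULTIPLIER` (4) sets the relapse hazard from stable
#' disease as a multiple of the relapse hazard from remission. All three are
#' structural assumptions of the published derivation, kept as named,
#' overridable constants rather than inline literals.
#'
#' @name deale-constants
#' @export
CYCLE_MONTH_FACTOR <- 0.75

#' @rdname deale-constants
#' @export
RR_SCALE <- 3

#' @rdname deale-constants
#' @export
STABLE_RELAPSE_MULTIPLIER <- 4

#' Risk fraction from survival medians
#'
#' `rr = (OS - PFS) / OS`: the fraction of overall survival spent after
#' progression-free survival has ended.
#'
#' @param os_months Median overall survival, months.
#' @param pfs_months Median progression-free survival, months.
#' @return A fraction in (0, 1).
#' @examples
#' derive_rr(24, 8.8)   # 0.6333..., prints as 0.63
#' derive_rr(22, 6.6)   # 0.70
#' @export
derive_rr <- function(os_months, pfs_months) {
  check_number(pfs_months, "pfs_months", min = 0, strict_min = TRUE)
  if (os_months <= pfs_months)
    stop_domain("os_months (%g) must exceed pfs_months (%g)",
                os_months, pfs_months)
  (os_months - pfs_months) / os_months
}

#' Per-cycle probability of moving from stable disease to remission
#'
#' `1 - exp(-rr / RR_SCALE)`.
#'
#' @param rr Risk fraction in \[0, 1\] (see [derive_rr()]).
#' @param rr_scale Divisor, default [RR_SCALE].
#' @return Probability per cycle.
#' @examples
#' p_stable_to_remission(0.63)  # 0.18941 -> 0.189 at 3 dp
#' @export
p_stable_to_remission <- function(rr, rr_scale = RR_SCALE) {
  check_number(rr, "rr", 0, 1)
  1 - exp(-rr / rr_scale)
}

#' Per-cycle probability of relapse from remission
#'
#' DEALE conversion of the median duration of response:
#' `1 - exp(-CYCLE_MONTH_FACTOR * ln(2) / dor_months)`.
#'
#' @param dor_months Median duration of response, months (> 0).
#' @param cycle_month_factor Cycle length factor, default
#'   [CYCLE_MONTH_FACTOR].
#' @return Probability per cycle.
#' @examples
#' p_remission_to_relapse(8.5)  # 0.059326 -> 0.059
#' @export
p_remission_to_relapse <- function(dor_months,
                                   cycle_month_factor = CYCLE_MONTH_FACTOR) {
  check_number(dor_months, "dor_months", min = 0, strict_min = TRUE)
  1 - exp(-cycle_month_factor * log(2) / dor_months)
}

#' Per-cycle probability of death from progressive disease
#'
#' DEALE conversion of post-progression survival `OS - PFS`:
#' `1 - exp(-CYCLE_MONTH_FACTOR * ln(2) / (os - pfs))`.
#'
#' @inheritParams derive_rr
#' @param cycle_month_factor Cycle length factor, default
#'   [CYCLE_MONTH_FACTOR].
#' @return Probability per cycle.
#' @examples
#' p_relapse_to_death(24, 8.8)  # 0.033624 -> 0.034
#' p_relapse_to_death(22, 6.6)  # 0.033195 -> 0.033
#' @export
p_relapse_to_death <- function(os_months, pfs_months,
                               cycle_month_factor = CYCLE_MONTH_FACTOR) {
  if (os_months <= pfs_months)
    stop_domain("os_months (%g) must exceed pfs_months (%g)",
                os_months, pfs_months)
  1 - exp(-cycle_month_factor * log(2) / (os_months - pfs_months))
}

#' Per-cycle probability of relapse directly from stable disease
#'
#' Assumed `STABLE_RELAPSE_MULTIPLIER` (4) times the relapse probability
#' from remission.
#'
#' @param p_rp Remission-to-relapse probability, in \[0, 1/multiplier\].
#' @param multiplier Hazard multiplier, default [STABLE_RELAPSE_MULTIPLIER].
#' @return Probability per cycle.
#' @examples
#' p_stable_to_relapse(0.059)  # 0.236
#' @export
p_stable_to_relapse <- function(p_rp, multiplier = STABLE_RELAPSE_MULTIPLIER) {
  check_number(p_rp, "p_rp", 0, 1)
  out <- multiplier * p_rp
  if (out > 1)
    stop_domain(
      "stable-to-relapse probability %g x %g = %g exceeds 1", multiplier,
      p_rp, out)
  out
}

## round half away from zero / truncate toward zero, at 3 decimals
round3 <- function(x, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  if (mode == "round") sign(x) * floor(abs(x) * 1000 + 0.5) / 1000
  else trunc(x * 1000) / 1000
}

#' Derive the four independent per-cycle probabilities of one arm
#'
#' Computes `p_sr` (stable to remission), `p_rp` (remission to relapse),
#' `p_pd` (relapse to death) and `p_sp` (stable to relapse, `4 * p_rp`). In
#' `rounding_mode = "paper_3dp"` each derived probability is rounded to 3
#' decimals *before* the multiple and the self-transition complements are
#' formed, reproducing published tables digit-for-digit; `three_dp` selects
#' rounding half-away-from-zero (default) or truncation at the third decimal
#' (needed to match one published arm; see the package vignette).
#'
#' @param clinical A [clinical_summary()].
#' @param rounding_mode `"full_precision"` or `"paper_3dp"`.
#' @param three_dp 3-decimal mode used by `"paper_3dp"`: `"round"` or
#'   `"truncate"`.
#' @param overrides Optional named numeric replacing individual derived
#'   probabilities (`p_sr`, `p_sp`, `p_rp`, `p_pd`) after derivation.
#' @return Named list `p_sr`, `p_sp`, `p_rp`, `p_pd`.
#' @export
derive_transition_probs <- function(clinical,
                                    rounding_mode = c("full_precision", "paper_3dp"),
                                    three_dp = c("round", "truncate"),
                                    overrides = NULL) {
  rounding_mode <- match.arg(rounding_mode)
  three_dp <- match.arg(three_dp)
  p_sr <- p_stable_to_remission(clinical$rr)
  p_rp <- p_remission_to_relapse(clinical$dor_months)
  p_pd <- p_relapse_to_death(clinical$os_months, clinical$pfs_months)
  if (rounding_mode == "paper_3dp") {
    p_sr <- round3(p_sr, three_dp)
    p_rp <- round3(p_rp, three_dp)
    p_pd <- round3(p_pd, three_dp)
  }
  p_sp <- p_stable_to_relapse(p_rp)
  pr <- list(p_sr = p_sr, p_sp = p_sp, p_rp = p_rp, p_pd = p_pd)
  for (nm in names(overrides)) {
    if (!nm %in% names(pr))
      stop_domain("cannot override unknown probability '%s'", nm)
    check_number(overrides[[nm]], nm, 0, 1)
    pr[[nm]] <- as.numeric(overrides[[nm]])
  }
  pr
}

#' Assemble the structural 4x4 transition matrix
#'
#' States are ordered `SD, RE, PD, DE`. Self-transitions are complements
#' (`p_ss = 1 - p_sr - p_sp`, `p_rr = 1 - p_rp`, `p_pp = 1 - p_pd`), death is
#' absorbing, and the structural zeros (no recovery from relapse, no death
#' directly from stable disease or remission) are enforced.
#'
#' @param probs Named list with `p_sr`, `p_sp`, `p_rp`, `p_pd` (as returned
#'   by [derive_transition_probs()]).
#' @return A `transition_matrix`: a 4x4 row-stochastic matrix with a
#'   `provenance` attribute mapping each nonzero entry to its defining
#'   formula.
#' @export
assemble_matrix <- function(probs) {
  p_sr <- probs$p_sr; p_sp <- probs$p_sp
  p_rp <- probs$p_rp; p_pd <- probs$p_pd
  ent <- c(p_ss = 1 - p_sr - p_sp, p_sr = p_sr, p_sp = p_sp,
           p_rr = 1 - p_rp, p_rp = p_rp, p_pp = 1 - p_pd, p_pd = p_pd)
  bad <- ent < -1e-12 | ent > 1 + 1e-12
  if (any(bad))
    stop_domain("transition probability '%s' = %g lies outside [0, 1]",
                names(ent)[which(bad)[1]], ent[which(bad)[1]])
  ent <- pmin(pmax(ent, 0), 1)
  m <- rbind(c(ent[["p_ss"]], ent[["p_sr"]], ent[["p_sp"]], 0),
             c(0, ent[["p_rr"]], ent[["p_rp"]], 0),
             c(0, 0, ent[["p_pp"]], ent[["p_pd"]]),
             c(0, 0, 0, 1))
  dimnames(m) <- list(STATES, STATES)
  prov <- data.frame(
    from = c("SD", "SD", "SD", "RE", "RE", "PD", "PD", "DE"),
    to   = c("SD", "RE", "PD", "RE", "PD", "PD", "DE", "DE"),
    probability = c(ent[["p_ss"]], p_sr, p_sp, ent[["p_rr"]], p_rp,
                    ent[["p_pp"]], p_pd, 1),
    formula = c("1 - p_sr - p_sp", "1 - exp(-rr/3)", "4 * p_rp",
                "1 - p_rp", "1 - exp(-0.75*ln2/DoR)", "1 - p_pd",
                "1 - exp(-0.75*ln2/(OS-PFS))", "absorbing"))
  structure(m, class = c("transition_matrix", class(m)), provenance = prov)
}

#' Build the per-cycle transition matrix of one arm
#'
#' Convenience wrapper: [derive_transition_probs()] followed by
#' [assemble_matrix()].
#'
#' @inheritParams derive_transition_probs
#' @return A `transition_matrix`.
#' @examples
#' nc <- paper_fixture("whole_group")$strategies$nc
#' build_matrix(nc$clinical, rounding_mode = "paper_3dp")
#' @export
build_matrix <- function(clinical,
                         rounding_mode = c("full_precision", "paper_3dp"),
                         three_dp = c("round", "truncate"),
                         overrides = NULL) {
  assemble_matrix(derive_transition_probs(clinical, rounding_mode, three_dp,
                                          overrides))
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("Per-cycle transition matrix (states SD, RE, PD, DE):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Export a transition matrix with formula provenance
#'
#' Writes one row per structural (nonzero) entry: from-state, to-state,
#' probability and the defining formula.
#'
#' @param tmat A `transition_matrix`.
#' @param path Output CSV path.
#' @return The provenance table, invisibly.
#' @export
export_matrix_csv <- function(tmat, path) {
  prov <- attr(tmat, "provenance")
  write.csv(prov, path, row.names = FALSE)
  invisible(prov)
}
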