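#' Incremental cost-effectiveness comparison
#'
#' Computes incremental cost, incremental QALYs and the ICER of an
#' intervention against a comparator, with the standard dominance
#' classification: `dominant` when the intervention is cheaper and more
#' effective, `dominated` when dearer and less effective, `equal_effect`
#' when the QALYs are tied (cost-minimisation verdict). Negative ICERs are
#' retained with their flag; reports print the magnitude plus the flag to
#' avoid sign ambiguity.
#'
#' @param cost_i,qaly_i intervention mean cost (MAD) and QALYs.
#' @param cost_c,qaly_c comparator mean cost and QALYs.
#' @param intervention,comparator identifiers for the report.
#' @param wtp willingness-to-pay threshold (MAD/QALY) used for the
#'   `cost_effective_at_wtp` field (net-monetary-benefit ordering).
#' @return a `cea_comparison` list with fields `intervention`, `comparator`,
#'   `delta_cost`, `delta_qaly`, `icer` (`NA` when QALYs are tied), `flag`
#'   (`dominant`, `dominated`, `equal_effect` or `trade_off`) and
#'   `cost_effective_at_wtp`.
#' @export
icer <- function(cost_i, qaly_i, cost_c, qaly_c,
                 intervention = "intervention", comparator = "comparator",
                 wtp = 250832.40) {
  dc <- cost_i - cost_c
  dq <- qaly_i - qaly_c
  flag <- if (dq == 0) "equal_effect"
  else if (dc < 0 && dq > 0) "dominant"
  else if (dc > 0 && dq < 0) "dominated"
  else "trade_off"
  structure(list(
    intervention = intervention, comparator = comparator,
    delta_cost = dc, delta_qaly = dq,
    icer = if (dq != 0) dc / dq else NA_real_,
    flag = flag,
    cost_effective_at_wtp = nmb(cost_i, qaly_i, wtp) >
      nmb(cost_c, qaly_c, wtp)
  ), class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  desc <- switch(x$flag,
    dominant = sprintf("dominant (ICER magnitude %.1f MAD/QALY)",
                       abs(x$icer)),
    dominated = sprintf("dominated (ICER magnitude %.1f MAD/QALY)",
                        abs(x$icer)),
    equal_effect = sprintf("equal effect; cost difference %.1f MAD",
                           x$delta_cost),
    sprintf("ICER %.1f MAD/QALY", x$icer))
  cat(sprintf("<cea_comparison> %s vs %s: dCost %.1f, dQALY %.4f -> %s\n",
              x$intervention, x$comparator, x$delta_cost, x$delta_qaly,
              desc))
  invisible(x)
}

#' Net monetary benefit
#'
#' `qaly * wtp - cost`; the linear decision statistic equivalent to the
#' ICER-versus-threshold rule.
#'
#' @param cost mean cost (MAD).
#' @param qaly mean QALYs.
#' @param wtp willingness to pay (MAD/QALY), must be non-negative.
#' @return MAD.
#' @export
nmb <- function(cost, qaly, wtp) {
  stopifnot(wtp >= 0)
  qaly * wtp - cost
}

#' Cost-effectiveness efficiency frontier
#'
#' Sorts strategies by cost (ties broken by QALY descending, then name),
#' flags strictly dominated strategies (another strategy is at least as
#' cheap and at least as effective, better on one margin; exact ties flag
#' the later name as weakly dominated) and extendedly dominated strategies
#' (removed where sequential ICERs along the frontier decrease), and
#' reports the sequential ICERs of the surviving frontier.
#'
#' @param results list of `cohort_result`s or a data frame with columns
#'   `strategy`, `cost`, `qaly`.
#' @return a data frame sorted by cost with columns `strategy`, `cost`,
#'   `qaly`, `status` (`frontier`, `dominated`, `weakly_dominated`,
#'   `extendedly_dominated`) and `icer_sequential` (`NA` off the frontier
#'   and for the cheapest frontier point).
#' @export
frontier <- function(results) {
  df <- if (is.data.frame(results)) results else cohort_results_df(results)
  if (nrow(df) < 2L) stopf("frontier needs at least 2 strategies")
  if (anyDuplicated(df$strategy)) stopf("duplicate strategy names")
  ord <- order(df$cost, -df$qaly, df$strategy)
  df <- df[ord, c("strategy", "cost", "qaly")]
  n <- nrow(df)
  status <- rep("frontier", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost[j] == df$cost[i] && df$qaly[j] == df$qaly[i]) {
        # identical points: the one later in the deterministic order loses
        if (j < i) status[i] <- "weakly_dominated"
      } else if (df$cost[j] <= df$cost[i] && df$qaly[j] >= df$qaly[i]) {
        status[i] <- "dominated"
        break
      }
    }
  }
  # extended dominance: drop points until sequential ICERs are
  # non-decreasing along the surviving chain
  repeat {
    keep <- which(status == "frontier")
    if (length(keep) < 3L) break
    ic <- diff(df$cost[keep]) / diff(df$qaly[keep])
    drop <- which(diff(ic) < 0)
    if (!length(drop)) break
    status[keep[drop[1L] + 1L]] <- "extendedly_dominated"
  }
  keep <- which(status == "frontier")
  icer_seq <- rep(NA_real_, n)
  if (length(keep) > 1L) {
    icer_seq[keep[-1L]] <- diff(df$cost[keep]) / diff(df$qaly[keep])
  }
  df$status <- status
  df$icer_sequential <- icer_seq
  rownames(df) <- NULL
  df
}
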