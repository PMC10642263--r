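#' Two-arm cost-effectiveness comparison
#'
#' Incremental statistics of an intervention versus a comparator:
#' incremental cost, life-years and QALYs, ICER per QALY and per LY,
#' incremental net health benefit \eqn{INHB = \Delta QALY - \Delta Cost/WTP}
#' (in QALYs) and incremental net monetary benefit
#' \eqn{NMB = WTP \cdot \Delta QALY - \Delta Cost} (in $). When
#' \eqn{|\Delta QALY| < 10^{-9}} the ICER is undefined (`NA`) and only the
#' dominance classification is meaningful.
#'
#' @param intervention,comparator Lists with elements `cost`, `ly`, `qaly`
#'   (as returned by [accrue_totals()]).
#' @param wtp Willingness-to-pay threshold, $ per QALY.
#' @param labels Length-2 character vector naming the two strategies.
#' @return A list of class `cea_comparison`.
#' @examples
#' compare_arms(list(cost = 33693, ly = 4.86, qaly = 2.72),
#'              list(cost = 15982, ly = 3.00, qaly = 1.67), wtp = 36289)
#' @export
compare_arms <- function(intervention, comparator, wtp,
                         labels = c("intervention", "comparator")) {
  stopifnot(is.numeric(wtp), wtp >= 0)
  dc <- intervention$cost - comparator$cost
  dl <- intervention$ly - comparator$ly
  dq <- intervention$qaly - comparator$qaly
  eps <- 1e-9
  icer_q <- if (abs(dq) < eps) NA_real_ else dc / dq
  icer_l <- if (abs(dl) < eps) NA_real_ else dc / dl
  dominance <-
    if (dq > eps && dc <= 0) "dominant"
    else if (dq < -eps && dc >= 0) "dominated"
    else if (abs(dq) < eps && abs(dc) < eps) "equivalent"
    else "trade-off"
  nmb <- wtp * dq - dc
  structure(list(labels = labels,
                 cost = c(intervention$cost, comparator$cost),
                 ly = c(intervention$ly, comparator$ly),
                 qaly = c(intervention$qaly, comparator$qaly),
                 delta_cost = dc, delta_ly = dl, delta_qaly = dq,
                 icer_per_qaly = icer_q, icer_per_ly = icer_l,
                 inhb_qaly = dq - dc / wtp,
                 nmb_delta = nmb,
                 dominance = dominance, wtp = wtp),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat("Cost-effectiveness comparison (WTP $", format(x$wtp, big.mark = ","),
      "/QALY)\n", sep = "")
  df <- data.frame(strategy = x$labels,
                   cost = sprintf("$%s", formatC(round(x$cost), format = "d",
                                                 big.mark = ",")),
                   LY = sprintf("%.2f", x$ly), QALY = sprintf("%.2f", x$qaly))
  print(df, row.names = FALSE)
  cat(sprintf("  incremental: cost $%s, %.2f LY, %.2f QALY\n",
              formatC(round(x$delta_cost), format = "d", big.mark = ","),
              x$delta_ly, x$delta_qaly))
  if (is.na(x$icer_per_qaly)) {
    cat("  ICER undefined (delta QALY ~ 0); classification:", x$dominance, "\n")
  } else {
    cat(sprintf("  ICER: $%s/QALY, $%s/LY (%s)\n",
                formatC(round(x$icer_per_qaly), format = "d", big.mark = ","),
                formatC(round(x$icer_per_ly), format = "d", big.mark = ","),
                x$dominance))
  }
  cat(sprintf("  INHB %.2f QALY, incremental NMB $%s => %scost-effective at WTP\n",
              x$inhb_qaly,
              formatC(round(x$nmb_delta), format = "d", big.mark = ","),
              if (is_cost_effective(x)) "" else "NOT "))
  invisible(x)
}

#' @export
as.data.frame.cea_comparison <- function(x, ...) {
  data.frame(intervention = x$labels[1], comparator = x$labels[2],
             cost_intervention = x$cost[1], cost_comparator = x$cost[2],
             ly_intervention = x$ly[1], ly_comparator = x$ly[2],
             qaly_intervention = x$qaly[1], qaly_comparator = x$qaly[2],
             delta_cost = x$delta_cost, delta_ly = x$delta_ly,
             delta_qaly = x$delta_qaly,
             icer_per_ly = x$icer_per_ly, icer_per_qaly = x$icer_per_qaly,
             inhb_qaly = x$inhb_qaly, nmb_delta = x$nmb_delta,
             dominance = x$dominance, wtp = x$wtp)
}

#' Is the intervention cost-effective?
#'
#' `TRUE` iff the incremental net monetary benefit is strictly positive
#' (equivalently INHB > 0). At `wtp` exactly equal to the ICER the NMB is
#' zero and the strategy is, by this strict convention, not deemed
#' cost-effective.
#'
#' @param comparison A `cea_comparison`.
#' @param wtp Threshold; defaults to the one stored in the comparison.
#' @return Logical.
#' @export
is_cost_effective <- function(comparison, wtp = comparison$wtp) {
  wtp * comparison$delta_qaly - comparison$delta_cost > 0
}

#' Run the base-case analysis
#'
#' Builds both arms from the configuration, runs the cohort model and
#' returns the two-arm comparison.
#'
#' @param config An `npccea_config` (default: [default_config()]).
#' @return A list of class `base_case` with elements `comparison`
#'   (a [compare_arms()] result), `totals` (per-arm accrual lists) and
#'   `traces` (per-arm cohort traces).
#' @examples
#' bc <- run_base_case()
#' bc$comparison
#' @export
run_base_case <- function(config = default_config()) {
  settings <- settings_from_config(config)
  arms <- list(tc = build_arm(config, "tc"), chemo = build_arm(config, "chemo"))
  traces <- lapply(arms, run_cohort, settings = settings)
  totals <- Map(accrue_totals, traces, arms, list(settings, settings))
  cmp <- compare_arms(totals$tc, totals$chemo, settings$wtp,
                      labels = c(arms$tc$name, arms$chemo$name))
  structure(list(comparison = cmp, totals = totals, traces = traces,
                 settings = settings), class = "base_case")
}

#' @export
print.base_case <- function(x, ...) print(x$comparison)
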