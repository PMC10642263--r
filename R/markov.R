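#' Model run settings
#'
#' Settings of the three-state cohort model. The defaults encode the
#' base-case analysis: 80 six-week cycles (`cycle_length_months = 1.5`, i.e.
#' exactly a 10-year horizon), 5% annual discounting applied as
#' \eqn{(1+r)^{-k c / 12}}, and a willingness-to-pay threshold of
#' $36,289/QALY (three times 2022 Chinese per-capita GDP).
#'
#' `survival_step_months` controls how far the fitted survival curves'
#' clock advances per model cycle. The curves are fitted with time in months;
#' the published totals are reproduced when the clock advances one month per
#' cycle (the indexing used by the original decision tree), which is the
#' default. Setting it equal to `cycle_length_months` gives the textbook
#' identification of model time with curve time.
#'
#' @param cycle_length_months Months of life accrued (and discounted) per
#'   model cycle.
#' @param n_cycles Number of cycles (>= 0).
#' @param discount_rate Annual discount rate in `[0, 0.08]`.
#' @param wtp Willingness-to-pay threshold, $ per QALY.
#' @param half_cycle_correction If `TRUE`, accruals weight the mean of the
#'   start- and end-of-cycle occupancies.
#' @param accrual `"cycle_start"` (default) or `"cycle_end"`: which state
#'   occupancy accrues a cycle's costs and outcomes (ignored when
#'   `half_cycle_correction = TRUE`).
#' @param survival_step_months Months advanced on the survival-curve clock
#'   per cycle.
#' @param chemo_duration_cycles Number of initial cycles during which the
#'   limited-duration chemotherapy backbone (gemcitabine + cisplatin) is
#'   costed; `NULL` (default) costs it for the whole progression-free stay.
#' @return A list of class `model_settings`.
#' @export
model_settings <- function(cycle_length_months = 1.5,
                           n_cycles = 80L,
                           discount_rate = 0.05,
                           wtp = 36289,
                           half_cycle_correction = FALSE,
                           accrual = c("cycle_start", "cycle_end"),
                           survival_step_months = 1.0,
                           chemo_duration_cycles = NULL) {
  accrual <- match.arg(accrual)
  stopifnot(cycle_length_months > 0, survival_step_months > 0,
            n_cycles >= 0, n_cycles == floor(n_cycles),
            discount_rate >= 0, discount_rate <= 0.08, wtp >= 0)
  structure(list(cycle_length_months = cycle_length_months,
                 n_cycles = as.integer(n_cycles),
                 discount_rate = discount_rate, wtp = wtp,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 accrual = accrual,
                 survival_step_months = survival_step_months,
                 chemo_duration_cycles = chemo_duration_cycles),
            class = "model_settings")
}

settings_from_config <- function(config) {
  m <- config$model
  model_settings(cycle_length_months = m$cycle_length_months,
                 n_cycles = m$n_cycles,
                 discount_rate = m$discount_rate$base,
                 wtp = m$wtp_per_qaly,
                 half_cycle_correction = isTRUE(m$half_cycle_correction),
                 accrual = if (is.null(m$accrual)) "cycle_start" else m$accrual,
                 survival_step_months = m$survival_step_months,
                 chemo_duration_cycles = m$chemo_duration_cycles)
}

#' Treatment-arm specification
#'
#' Bundles one strategy's survival curves, per-cycle costs, adverse-event
#' profile and utilities. Usually built from a configuration with
#' [build_arm()]; the explicit constructor is exposed for custom analyses.
#'
#' @param name Arm label.
#' @param os_curve,pfs_curve Overall- and progression-free-survival
#'   [surv_curve()]s.
#' @param drug_cost_continuous $ per cycle of drugs given until progression
#'   while progression-free (e.g. tislelizumab maintenance).
#' @param drug_cost_limited $ per cycle of the limited-duration chemotherapy
#'   backbone (costed per `chemo_duration_cycles` of the settings).
#' @param routine_pfs_cost,routine_pd_cost $ per cycle of routine care
#'   (laboratory, imaging, administration) attached to each living state.
#' @param bsc_cost $ per cycle of best supportive care in the progressed
#'   state.
#' @param second_line_cost $ per cycle of second-line therapy in the
#'   progressed state, weighted by `post_discontinuation_rate`.
#' @param post_discontinuation_rate Fraction of progressed patients receiving
#'   subsequent active therapy, in `[0, 1]`.
#' @param terminal_care_cost One-time $ cost per death.
#' @param ae_risks,ae_costs Named vectors of grade >= 3 adverse-event risks
#'   and unit costs; their dot product is charged once at model entry, as is
#'   the one-time `ae_disutility` QALY decrement.
#' @param ae_disutility One-time QALY decrement for adverse events.
#' @param utility_pfs,utility_pd Health-state utilities in `[0, 1]`.
#' @return A list of class `arm_spec`.
#' @export
arm_spec <- function(name, os_curve, pfs_curve,
                     drug_cost_continuous = 0, drug_cost_limited = 0,
                     routine_pfs_cost = 0, routine_pd_cost = 0,
                     bsc_cost = 0, second_line_cost = 0,
                     post_discontinuation_rate = 0,
                     terminal_care_cost = 0,
                     ae_risks = numeric(), ae_costs = numeric(),
                     ae_disutility = 0,
                     utility_pfs = 1, utility_pd = 1) {
  stopifnot(inherits(os_curve, c("surv_curve", "surv_curve_ph")),
            inherits(pfs_curve, c("surv_curve", "surv_curve_ph")),
            post_discontinuation_rate >= 0, post_discontinuation_rate <= 1,
            utility_pfs >= 0, utility_pfs <= 1,
            utility_pd >= 0, utility_pd <= 1,
            all(ae_risks >= 0 & ae_risks <= 1), all(ae_costs >= 0),
            drug_cost_continuous >= 0, drug_cost_limited >= 0,
            routine_pfs_cost >= 0, routine_pd_cost >= 0, bsc_cost >= 0,
            second_line_cost >= 0, terminal_care_cost >= 0)
  if (length(ae_risks)) {
    stopifnot(!is.null(names(ae_risks)),
              all(names(ae_risks) %in% names(ae_costs)))
    ae_costs <- ae_costs[names(ae_risks)]
  }
  structure(list(name = name, os_curve = os_curve, pfs_curve = pfs_curve,
                 drug_cost_continuous = drug_cost_continuous,
                 drug_cost_limited = drug_cost_limited,
                 routine_pfs_cost = routine_pfs_cost,
                 routine_pd_cost = routine_pd_cost,
                 bsc_cost = bsc_cost, second_line_cost = second_line_cost,
                 post_discontinuation_rate = post_discontinuation_rate,
                 terminal_care_cost = terminal_care_cost,
                 ae_risks = ae_risks, ae_costs = ae_costs,
                 ae_disutility = ae_disutility,
                 utility_pfs = utility_pfs, utility_pd = utility_pd),
            class = "arm_spec")
}

#' One-time adverse-event cost of an arm
#'
#' Dot product of grade >= 3 adverse-event risks and unit management costs,
#' charged once to the whole cohort at model entry.
#'
#' @param arm An `arm_spec`.
#' @return A single $ amount.
#' @export
ae_onetime_cost <- function(arm) {
  if (!length(arm$ae_risks)) return(0)
  sum(arm$ae_risks * arm$ae_costs)
}

#' Build an arm from a configuration
#'
#' @param config An `npccea_config`.
#' @param arm `"tc"` (tislelizumab plus chemotherapy) or `"chemo"`.
#' @return An [arm_spec()].
#' @export
build_arm <- function(config, arm = c("tc", "chemo")) {
  arm <- match.arg(arm)
  a <- config$arms[[arm]]
  cv <- config$curves[[arm]]
  drug_base <- function(d) config$costs$drugs[[d]]$base
  limited <- intersect(a$drugs, c("gemcitabine", "cisplatin"))
  continuous <- setdiff(a$drugs, limited)
  routine <- sum(vapply(config$costs$routine, `[[`, numeric(1), "base"))
  states <- config$model$routine_cost_states
  risks <- vapply(a$ae_risks, `[[`, numeric(1), "base")
  costs <- vapply(config$costs$ae, `[[`, numeric(1), "base")
  arm_spec(
    name = a$label,
    os_curve = surv_curve(cv$os$family, cv$os$scale, cv$os$shape),
    pfs_curve = surv_curve(cv$pfs$family, cv$pfs$scale, cv$pfs$shape),
    drug_cost_continuous = sum(vapply(continuous, drug_base, numeric(1))),
    drug_cost_limited = sum(vapply(limited, drug_base, numeric(1))),
    routine_pfs_cost = if ("pfs" %in% states) routine else 0,
    routine_pd_cost = if ("pd" %in% states) routine else 0,
    bsc_cost = config$costs$best_supportive_care$base,
    second_line_cost = config$costs$drugs$second_line$base,
    post_discontinuation_rate = a$post_discontinuation_rate$base,
    terminal_care_cost = config$costs$terminal_care$base,
    ae_risks = risks, ae_costs = costs,
    ae_disutility = a$ae_disutility$base,
    utility_pfs = config$utilities$pfs$base,
    utility_pd = config$utilities$pd$base)
}

#' Per-cycle transition probabilities of an arm
#'
#' Exit probabilities for cycle `k`: `p_death` from the overall-survival
#' curve, `p_pfs_exit` from the progression-free-survival curve, and the
#' progression probability `p_pd = max(0, p_pfs_exit - p_death)`. The death
#' probability is applied identically from both living states (the model has
#' no state-specific mortality beyond the marginal OS curve).
#'
#' @param arm An `arm_spec`.
#' @param k Cycle index (vector allowed), `k >= 1`.
#' @param settings A [model_settings()].
#' @return A data frame with columns `cycle`, `p_pfs_exit`, `p_death`,
#'   `p_pd`.
#' @export
transition_probs <- function(arm, k, settings) {
  s <- settings$survival_step_months
  p_exit <- cycle_transition_prob(arm$pfs_curve, k, s)
  p_death <- cycle_transition_prob(arm$os_curve, k, s)
  data.frame(cycle = k, p_pfs_exit = p_exit, p_death = p_death,
             p_pd = pmax(0, p_exit - p_death))
}

#' Run the three-state cohort model for one arm
#'
#' Propagates the cohort (all starting progression-free) through
#' `n_cycles` cycles. Death is absorbing and no backward transitions exist;
#' state occupancies sum to one at every cycle. Discounted cost,
#' life-year and QALY accruals are attached per cycle; one-time quantities
#' (adverse-event cost and disutility, charged at entry) appear in the
#' first row's accrual columns.
#'
#' @param arm An `arm_spec`.
#' @param settings A [model_settings()].
#' @return A data frame of class `cohort_trace` with one row per cycle:
#'   `cycle`, `t_months`, `pfs`, `pd`, `death` (end-of-cycle occupancies),
#'   `new_deaths`, `disc_cost`, `disc_ly`, `disc_qaly`.
#' @export
run_cohort <- function(arm, settings = model_settings()) {
  K <- settings$n_cycles
  empty <- data.frame(cycle = integer(), t_months = numeric(),
                      pfs = numeric(), pd = numeric(), death = numeric(),
                      new_deaths = numeric(), disc_cost = numeric(),
                      disc_ly = numeric(), disc_qaly = numeric())
  if (K == 0L) return(structure(empty, class = c("cohort_trace", "data.frame")))
  k <- seq_len(K)
  tp <- transition_probs(arm, k, settings)
  pfs <- cumprod(1 - tp$p_death - tp$p_pd)
  alive <- cumprod(1 - tp$p_death)
  pd <- alive - pfs
  death <- 1 - alive
  trace <- data.frame(cycle = k,
                      t_months = k * settings$cycle_length_months,
                      pfs = pfs, pd = pd, death = death,
                      new_deaths = diff(c(0, death)))
  acc <- cycle_accruals(trace, arm, settings)
  trace$disc_cost <- acc$cost
  trace$disc_ly <- acc$ly
  trace$disc_qaly <- acc$qaly
  structure(trace, class = c("cohort_trace", "data.frame"))
}

# occupancy weights per the accrual convention
occ_weights <- function(trace, settings) {
  K <- nrow(trace)
  pfs_end <- trace$pfs; pd_end <- trace$pd
  pfs_start <- c(1, pfs_end[-K]); pd_start <- c(0, pd_end[-K])
  if (settings$half_cycle_correction) {
    list(pfs = (pfs_start + pfs_end) / 2, pd = (pd_start + pd_end) / 2)
  } else if (settings$accrual == "cycle_start") {
    list(pfs = pfs_start, pd = pd_start)
  } else {
    list(pfs = pfs_end, pd = pd_end)
  }
}

# per-cycle discounted accruals; one-time entry quantities are loaded onto
# the first cycle undiscounted (they occur at t = 0)
cycle_accruals <- function(trace, arm, settings) {
  K <- nrow(trace)
  if (K == 0L) return(list(cost = numeric(), ly = numeric(), qaly = numeric()))
  k <- trace$cycle
  w <- occ_weights(trace, settings)
  pfs_w <- w$pfs; pd_w <- w$pd
  cyc_years <- settings$cycle_length_months / 12
  disc <- (1 + settings$discount_rate)^(-(k * settings$cycle_length_months) / 12)
  dur <- settings$chemo_duration_cycles
  drug <- arm$drug_cost_continuous +
    arm$drug_cost_limited * (if (is.null(dur)) 1 else as.numeric(k <= dur))
  cost <- pfs_w * (drug + arm$routine_pfs_cost) +
    pd_w * (arm$routine_pd_cost + arm$bsc_cost +
            arm$second_line_cost * arm$post_discontinuation_rate) +
    trace$new_deaths * arm$terminal_care_cost
  ly <- (pfs_w + pd_w) * cyc_years
  qaly <- (pfs_w * arm$utility_pfs + pd_w * arm$utility_pd) * cyc_years
  cost <- cost * disc; ly <- ly * disc; qaly <- qaly * disc
  cost[1] <- cost[1] + ae_onetime_cost(arm)
  qaly[1] <- qaly[1] - arm$ae_disutility
  list(cost = cost, ly = ly, qaly = qaly)
}

#' Total discounted cost, life-years and QALYs of a trace
#'
#' Re-derives the per-cycle accruals from the trace occupancies (so any
#' modified trace can be re-costed) and sums them, including the one-time
#' adverse-event cost and disutility at entry.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param arm The `arm_spec` that produced it.
#' @param settings The [model_settings()] used.
#' @return A list with elements `cost`, `ly`, `qaly`.
#' @export
accrue_totals <- function(trace, arm, settings) {
  acc <- cycle_accruals(trace, arm, settings)
  list(cost = sum(acc$cost), ly = sum(acc$ly), qaly = sum(acc$qaly))
}

#' Write a cohort trace as CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
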