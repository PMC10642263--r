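#' @importFrom stats rbeta rgamma runif sd
NULL

# ---- distribution machinery ------------------------------------------------

# SD convention for probabilistic sampling: the printed (low, high) range is
# treated as a ~95% interval, SD = (high - low) / (2 * 1.96)
range_sd <- function(low, high) (high - low) / (2 * 1.96)

beta_moments <- function(mean, sd) {
  v <- mean * (1 - mean) / sd^2 - 1
  if (v <= 0) return(NULL)      # SD too large for the beta support
  c(shape1 = mean * v, shape2 = (1 - mean) * v)
}

gamma_moments <- function(mean, sd) {
  c(shape = mean^2 / sd^2, rate = mean / sd^2)
}

# n draws for one parameter-table row
draw_parameter <- function(row, n) {
  m <- row$base; lo <- row$low; hi <- row$high
  if (row$dist == "fixed" || lo == hi) return(rep.int(m, n))
  s <- range_sd(lo, hi)
  switch(row$dist,
    uniform = runif(n, lo, hi),
    beta = {
      ab <- beta_moments(m, s)
      if (is.null(ab)) {
        warning("beta method-of-moments infeasible for '", row$parameter,
                "'; falling back to uniform on [low, high]")
        runif(n, lo, hi)
      } else rbeta(n, ab[1], ab[2])
    },
    gamma = {
      if (m <= 0) rep.int(m, n) else {
        sr <- gamma_moments(m, s); rgamma(n, sr[1], sr[2])
      }
    },
    stop("unknown distribution '", row$dist, "'"))
}

#' Sample uncertain parameters
#'
#' Draws values for every row of a [parameter_table()]: beta and gamma
#' distributions parameterised by method of moments from
#' `(mean = base, SD = (high - low)/(2 * 1.96))`, uniform on `[low, high]`
#' for the discount rate, and the base value for fixed/degenerate rows.
#' If the beta method of moments is infeasible the draw falls back to a
#' uniform on the range, with a warning.
#'
#' @param specs A parameter table (data frame with `parameter`, `base`,
#'   `low`, `high`, `dist`).
#' @param n Number of draws.
#' @param seed Optional integer seed (set once before sampling; draws are
#'   generated row by row in table order, so a given seed is reproducible).
#' @return An `n` x `nrow(specs)` matrix with one column per parameter.
#' @export
sample_parameters <- function(specs, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(seq_len(nrow(specs)),
                  function(i) draw_parameter(specs[i, ], n),
                  numeric(n))
  draws <- matrix(draws, nrow = n,
                  dimnames = list(NULL, specs$parameter))
  draws
}

# ---- fast model evaluation for PSA ----------------------------------------

# Precomputes everything that does not depend on sampled parameters (the
# survival curves carry no printed uncertainty, so state occupancies are
# fixed) and returns a closure evaluating both arms for one draw.
psa_engine <- function(config, arms = NULL, specs = parameter_table(config)) {
  settings <- settings_from_config(config)
  if (is.null(arms))
    arms <- list(tc = build_arm(config, "tc"), chemo = build_arm(config, "chemo"))
  K <- settings$n_cycles
  k <- seq_len(K)
  cyc_years <- settings$cycle_length_months / 12
  t_years <- (k * settings$cycle_length_months) / 12
  ix <- function(path) {
    i <- match(path, specs$parameter)
    if (is.na(i)) stop("parameter not in table: ", path)
    i
  }
  dur <- settings$chemo_duration_cycles
  limited_mask <- if (is.null(dur)) rep(1, K) else as.numeric(k <= dur)
  routine_ix <- vapply(paste0("costs/routine/",
                              names(config$costs$routine)), ix, 1L)
  states <- config$model$routine_cost_states
  arm_ctx <- lapply(names(arms), function(a) {
    arm <- arms[[a]]
    tr <- run_cohort(arm, settings)
    w <- occ_weights(tr, settings)
    acfg <- config$arms[[a]]
    limited <- intersect(acfg$drugs, c("gemcitabine", "cisplatin"))
    continuous <- setdiff(acfg$drugs, limited)
    ixv <- function(paths) if (length(paths)) vapply(paths, ix, 1L) else integer(0)
    list(pfs_w = w$pfs, pd_w = w$pd, nd = tr$new_deaths,
         cont_ix = ixv(if (length(continuous)) paste0("costs/drugs/", continuous)),
         lim_ix = ixv(if (length(limited)) paste0("costs/drugs/", limited)),
         risk_ix = vapply(paste0("arms/", a, "/ae_risks/",
                                 names(acfg$ae_risks)), ix, 1L),
         aecost_ix = vapply(paste0("costs/ae/", names(acfg$ae_risks)), ix, 1L),
         pdr_ix = ix(paste0("arms/", a, "/post_discontinuation_rate")),
         disu_ix = ix(paste0("arms/", a, "/ae_disutility")))
  })
  names(arm_ctx) <- names(arms)
  i_disc <- ix("model/discount_rate")
  i_upfs <- ix("utilities/pfs"); i_upd <- ix("utilities/pd")
  i_sl <- ix("costs/drugs/second_line")
  i_bsc <- ix("costs/best_supportive_care"); i_term <- ix("costs/terminal_care")

  eval_one <- function(v) {
    v <- unname(v)
    disc <- (1 + v[i_disc])^(-t_years)
    routine <- sum(v[routine_ix])
    r_pfs <- if ("pfs" %in% states) routine else 0
    r_pd <- if ("pd" %in% states) routine else 0
    out <- lapply(arm_ctx, function(cx) {
      drug <- sum(v[cx$cont_ix]) + sum(v[cx$lim_ix]) * limited_mask
      cost <- sum((cx$pfs_w * (drug + r_pfs) +
                   cx$pd_w * (r_pd + v[i_bsc] + v[i_sl] * v[cx$pdr_ix]) +
                   cx$nd * v[i_term]) * disc) +
        sum(v[cx$risk_ix] * v[cx$aecost_ix])
      qaly <- sum((cx$pfs_w * v[i_upfs] + cx$pd_w * v[i_upd]) *
                  cyc_years * disc) - v[cx$disu_ix]
      ly <- sum((cx$pfs_w + cx$pd_w) * cyc_years * disc)
      c(cost = cost, ly = ly, qaly = qaly)
    })
    c(cost_tc = out$tc[["cost"]], qaly_tc = out$tc[["qaly"]],
      ly_tc = out$tc[["ly"]],
      cost_chemo = out$chemo[["cost"]], qaly_chemo = out$chemo[["qaly"]],
      ly_chemo = out$chemo[["ly"]])
  }
  list(eval = eval_one, specs = specs, settings = settings)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo resampling of every uncertain input (see
#' [sample_parameters()]) with a full model evaluation per iteration.
#' Parameters shared between the two arms (utilities, unit costs, discount
#' rate) are sampled once per iteration and applied to both; arm-specific
#' parameters are sampled independently. The survival curves carry no
#' printed uncertainty and are held at their fitted values.
#'
#' @param config An `npccea_config`.
#' @param n_iter Number of iterations (default 10,000).
#' @param seed Integer seed; the same seed reproduces the run exactly.
#' @param arms Optional named list `list(tc = , chemo = )` of [arm_spec()]s
#'   overriding the configuration's arms (used for subgroup analyses).
#' @return An object of class `psa_result`: a list with `results` (data
#'   frame `iter`, `delta_cost`, `delta_qaly`), `prob_ce` (fraction of
#'   iterations with positive incremental net monetary benefit at the
#'   configuration's WTP), `wtp`, `n_iter`, `seed`.
#' @export
run_psa <- function(config = default_config(), n_iter = 10000, seed = 1,
                    arms = NULL) {
  stopifnot(n_iter >= 1)
  eng <- psa_engine(config, arms = arms)
  draws <- sample_parameters(eng$specs, n = n_iter, seed = seed)
  out <- apply(draws, 1, eng$eval)
  dc <- out["cost_tc", ] - out["cost_chemo", ]
  dq <- out["qaly_tc", ] - out["qaly_chemo", ]
  wtp <- eng$settings$wtp
  structure(list(results = data.frame(iter = seq_len(n_iter),
                                      delta_cost = dc, delta_qaly = dq),
                 draws = draws,
                 prob_ce = mean(wtp * dq - dc > 0),
                 wtp = wtp, n_iter = n_iter, seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (seed %d)\n", x$n_iter, x$seed))
  cat(sprintf("  mean delta cost $%s, mean delta QALY %.3f\n",
              formatC(round(mean(x$results$delta_cost)), format = "d",
                      big.mark = ","), mean(x$results$delta_qaly)))
  cat(sprintf("  P(cost-effective at WTP $%s/QALY) = %.1f%%\n",
              formatC(x$wtp, format = "d", big.mark = ","), 100 * x$prob_ce))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA iterations with positive incremental net monetary benefit
#' across a grid of willingness-to-pay values.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Vector of WTP values; default 0 to twice the analysis
#'   threshold in 100 steps.
#' @return Data frame with columns `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 2 * psa$wtp, length.out = 101)) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa$results) > 0)
  dc <- psa$results$delta_cost; dq <- psa$results$delta_qaly
  prob <- vapply(wtp_grid, function(w) mean(w * dq - dc > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

# ---- one-way deterministic sensitivity ------------------------------------

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the base case with each uncertain parameter alone set to its low
#' and high bound. The tornado span is `|icer_high - icer_low|`; rows are
#' sorted by descending span with alphabetical tie-break. A perturbation
#' that drives the incremental QALY to zero or below leaves the ICER
#' undefined; such rows are flagged (`excluded = TRUE`), warned about, and
#' placed last regardless of span.
#'
#' @param config An `npccea_config`.
#' @param parameters Optional character vector restricting the analysis to a
#'   subset of [parameter_table()] paths.
#' @return A data frame of class `owsa_result` with columns `parameter`,
#'   `low_value`, `high_value`, `icer_low`, `icer_high`, `span`, `excluded`;
#'   the base-case ICER is attached as attribute `base_icer`.
#' @export
owsa <- function(config = default_config(), parameters = NULL) {
  ptab <- parameter_table(config)
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, ptab$parameter)
    if (length(missing)) stop("unknown parameter(s): ",
                              paste(missing, collapse = ", "))
    ptab <- ptab[ptab$parameter %in% parameters, , drop = FALSE]
  }
  base <- run_base_case(config)
  icer_at <- function(path, value) {
    cmp <- run_base_case(config_set(config, path, value))$comparison
    c(icer = cmp$icer_per_qaly, dq = cmp$delta_qaly)
  }
  res <- lapply(seq_len(nrow(ptab)), function(i) {
    row <- ptab[i, ]
    lo <- icer_at(row$parameter, row$low)
    hi <- icer_at(row$parameter, row$high)
    bad <- is.na(lo["icer"]) || is.na(hi["icer"]) ||
      lo["dq"] <= 0 || hi["dq"] <= 0
    data.frame(parameter = row$parameter,
               low_value = row$low, high_value = row$high,
               icer_low = unname(lo["icer"]), icer_high = unname(hi["icer"]),
               span = if (bad) NA_real_ else abs(hi[["icer"]] - lo[["icer"]]),
               excluded = bad)
  })
  res <- do.call(rbind, res)
  if (any(res$excluded))
    warning("excluded from tornado ordering (incremental QALY <= 0 under ",
            "perturbation): ",
            paste(res$parameter[res$excluded], collapse = ", "))
  res <- res[order(res$excluded, -ifelse(is.na(res$span), -Inf, res$span),
                   res$parameter), ]
  rownames(res) <- NULL
  attr(res, "base_icer") <- base$comparison$icer_per_qaly
  class(res) <- c("owsa_result", "data.frame")
  res
}
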