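# Configuration: every model input with its base value, deterministic
# sensitivity range and sampling distribution, mirroring the published
# parameter table. Costs are 2022 US dollars (exchange rate CNY 7.0848 per
# USD kept as metadata only); probabilities and utilities dimensionless;
# survival scale/shape in months.

pv <- function(base, low, high, dist) {
  list(base = base, low = low, high = high, dist = dist)
}

#' Default model configuration
#'
#' Builds the shipped parameter set for the comparison of first-line
#' tislelizumab plus gemcitabine-cisplatin (arm `tc`) versus
#' gemcitabine-cisplatin alone (arm `chemo`) in recurrent/metastatic
#' nasopharyngeal carcinoma. Each uncertain scalar carries `base`, `low`,
#' `high` (the printed ranges, +/-20% of base except the discount rate) and a
#' sampling distribution (`gamma` for costs, `beta` for probabilities and
#' utilities, `uniform` for the discount rate).
#'
#' The `model` block holds the run settings: 80 six-week cycles
#' (`cycle_length_months = 1.5`, exactly a 10-year horizon), a 5% annual
#' discount rate, a willingness-to-pay threshold of $36,289/QALY, and the
#' time-indexing calibration `survival_step_months = 1` under which the
#' months-fitted Weibull curves are advanced one month per model cycle
#' (see the package vignette for why this reproduces the published totals).
#'
#' @return A nested list of class `npccea_config`.
#' @export
default_config <- function() {
  cfg <- list(
    model = list(
      cycle_length_months = 1.5,
      survival_step_months = 1.0,
      n_cycles = 80L,
      discount_rate = pv(0.05, 0.00, 0.08, "uniform"),
      wtp_per_qaly = 36289,
      half_cycle_correction = FALSE,
      accrual = "cycle_start",
      chemo_duration_cycles = NULL,   # NULL = until progression
      routine_cost_states = c("pfs", "pd"),
      ae_timing = "one_time_entry"
    ),
    exchange_rate_cny_per_usd = 7.0848,
    trial = list(overall_pfs_hr = 0.52),
    curves = list(
      tc = list(
        os  = list(family = "weibull", scale = 0.005008, shape = 1.297713),
        pfs = list(family = "weibull", scale = 0.075560, shape = 0.950960)),
      chemo = list(
        os  = list(family = "weibull", scale = 0.001060, shape = 2.027554),
        pfs = list(family = "weibull", scale = 0.034444, shape = 1.615226))
    ),
    utilities = list(
      pfs = pv(0.650, 0.520, 0.780, "beta"),
      pd  = pv(0.520, 0.416, 0.624, "beta")
    ),
    arms = list(
      tc = list(
        label = "Tislelizumab plus chemotherapy",
        drugs = c("tislelizumab", "gemcitabine", "cisplatin"),
        post_discontinuation_rate = pv(0.520, 0.416, 0.624, "beta"),
        ae_disutility = pv(0.0070, 0.0056, 0.0084, "beta"),
        ae_risks = list(
          lymphocyte_count_decreased   = pv(0.107, 0.086, 0.128, "beta"),
          platelet_count_decreased     = pv(0.206, 0.165, 0.247, "beta"),
          leukopenia                   = pv(0.206, 0.165, 0.247, "beta"),
          neutropenia                  = pv(0.214, 0.171, 0.257, "beta"),
          neutrophil_count_decreased   = pv(0.275, 0.220, 0.330, "beta"),
          anemia                       = pv(0.298, 0.238, 0.358, "beta"),
          white_blood_cell_count_decreased = pv(0.313, 0.250, 0.376, "beta"))
      ),
      chemo = list(
        label = "Chemotherapy",
        drugs = c("gemcitabine", "cisplatin"),
        post_discontinuation_rate = pv(0.720, 0.576, 0.864, "beta"),
        ae_disutility = pv(0.0069, 0.0055, 0.0083, "beta"),
        ae_risks = list(
          lymphocyte_count_decreased   = pv(0.121, 0.097, 0.145, "beta"),
          leukopenia                   = pv(0.159, 0.127, 0.191, "beta"),
          neutropenia                  = pv(0.189, 0.151, 0.227, "beta"),
          platelet_count_decreased     = pv(0.258, 0.206, 0.310, "beta"),
          anemia                       = pv(0.273, 0.218, 0.328, "beta"),
          neutrophil_count_decreased   = pv(0.348, 0.278, 0.418, "beta"),
          white_blood_cell_count_decreased = pv(0.371, 0.297, 0.445, "beta"))
      )
    ),
    costs = list(
      drugs = list(
        tislelizumab = pv(778, 622, 934, "gamma"),
        gemcitabine  = pv(39, 31, 47, "gamma"),
        cisplatin    = pv(31, 25, 37, "gamma"),
        second_line  = pv(77, 62, 92, "gamma")),
      ae = list(
        leukopenia                   = pv(100, 80, 120, "gamma"),
        lymphocyte_count_decreased   = pv(100, 80, 120, "gamma"),
        neutropenia                  = pv(466, 373, 559, "gamma"),
        white_blood_cell_count_decreased = pv(466, 373, 559, "gamma"),
        neutrophil_count_decreased   = pv(466, 373, 559, "gamma"),
        anemia                       = pv(537, 430, 644, "gamma"),
        platelet_count_decreased     = pv(3588, 2870, 4306, "gamma")),
      routine = list(
        laboratory     = pv(97, 78, 116, "gamma"),
        tumor_imaging  = pv(208, 166, 250, "gamma"),
        administration = pv(48, 38, 58, "gamma")),
      best_supportive_care = pv(142, 114, 170, "gamma"),
      terminal_care        = pv(1833, 1466, 2200, "gamma")
    ),
    subgroups = list(
      list(label = "Age < 65",            pfs_hr = 0.45, ci = c(0.33, 0.62)),
      list(label = "Male",                pfs_hr = 0.51, ci = c(0.36, 0.71)),
      list(label = "Female",              pfs_hr = 0.44, ci = c(0.23, 0.83)),
      list(label = "ECOG PS 0",           pfs_hr = 0.46, ci = c(0.28, 0.74)),
      list(label = "ECOG PS 1",           pfs_hr = 0.51, ci = c(0.35, 0.75)),
      list(label = "Never smoker",        pfs_hr = 0.38, ci = c(0.25, 0.58)),
      list(label = "Former smoker",       pfs_hr = 0.66, ci = c(0.41, 1.06)),
      list(label = "Primary metastatic",  pfs_hr = 0.53, ci = c(0.39, 0.71)),
      list(label = "Liver metastases",    pfs_hr = 0.48, ci = c(0.31, 0.74)),
      list(label = "No liver metastases", pfs_hr = 0.53, ci = c(0.35, 0.80)),
      list(label = "EBV DNA < 500 IU/mL", pfs_hr = 0.55, ci = c(0.28, 1.07)),
      list(label = "EBV DNA >= 500 IU/mL", pfs_hr = 0.46, ci = c(0.32, 0.64)),
      list(label = "PD-L1 < 10%",         pfs_hr = 0.46, ci = c(0.26, 0.81)),
      list(label = "PD-L1 >= 10%",        pfs_hr = 0.47, ci = c(0.32, 0.68))
    ),
    scenario = list(
      copayment = list(gemcitabine = 0.20, cisplatin = 0.00,
                       capecitabine = 0.05)
    )
  )
  class(cfg) <- c("npccea_config", "list")
  validate_config(cfg)
  cfg
}

#' Load a configuration from YAML
#'
#' Reads a YAML file with the same structure as [default_config()] (see
#' `system.file("extdata", "config_default.yaml", package = "npccea")`),
#' validates it exhaustively and returns it.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `npccea_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  # yaml reads drugs lists as list(); normalise to character vectors
  for (a in names(cfg$arms))
    cfg$arms[[a]]$drugs <- as.character(unlist(cfg$arms[[a]]$drugs))
  cfg$model$routine_cost_states <-
    as.character(unlist(cfg$model$routine_cost_states))
  if (!is.null(cfg$model$n_cycles)) cfg$model$n_cycles <- as.integer(cfg$model$n_cycles)
  class(cfg) <- c("npccea_config", "list")
  validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#'
#' Inverse of [load_config()]; the round trip `load_config(write_config(x))`
#' is value-identical.
#'
#' @param config An `npccea_config` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

valid_dists <- c("beta", "gamma", "uniform", "fixed")

check_pv <- function(x, name, max = Inf, errs) {
  for (f in c("base", "low", "high", "dist")) {
    if (is.null(x[[f]])) return(c(errs, sprintf("%s: missing field '%s'", name, f)))
  }
  if (!x$dist %in% valid_dists)
    errs <- c(errs, sprintf("%s: unknown distribution '%s'", name, x$dist))
  if (x$low > x$high)
    errs <- c(errs, sprintf("%s: low (%g) > high (%g)", name, x$low, x$high))
  else if (x$base < x$low || x$base > x$high)
    errs <- c(errs, sprintf("%s: base (%g) outside [low, high]", name, x$base))
  if (x$base < 0) errs <- c(errs, sprintf("%s: negative value", name))
  if (x$high > max)
    errs <- c(errs, sprintf("%s: value exceeds %g", name, max))
  errs
}

#' Validate a configuration
#'
#' Checks presence and coherence of every model input (ranges ordered,
#' probabilities and utilities within `[0, 1]`, known distributions, valid
#' survival-curve parameters, settings within their admissible ranges) and
#' reports all violations at once.
#'
#' @param config A configuration list.
#' @return `config`, invisibly, or an error listing every violation.
#' @export
validate_config <- function(config) {
  errs <- character()
  m <- config$model
  for (f in c("cycle_length_months", "survival_step_months", "n_cycles",
              "discount_rate", "wtp_per_qaly"))
    if (is.null(m[[f]])) errs <- c(errs, paste0("model: missing field '", f, "'"))
  if (length(errs) == 0) {
    if (m$cycle_length_months <= 0) errs <- c(errs, "model: cycle_length_months must be > 0")
    if (m$survival_step_months <= 0) errs <- c(errs, "model: survival_step_months must be > 0")
    if (m$n_cycles < 0) errs <- c(errs, "model: n_cycles must be >= 0")
    errs <- check_pv(m$discount_rate, "model/discount_rate", max = 0.08, errs)
    if (!is.null(m$accrual) && !m$accrual %in% c("cycle_start", "cycle_end"))
      errs <- c(errs, "model: accrual must be 'cycle_start' or 'cycle_end'")
    if (!all(m$routine_cost_states %in% c("pfs", "pd")))
      errs <- c(errs, "model: routine_cost_states must be a subset of {pfs, pd}")
  }
  for (a in c("tc", "chemo")) {
    for (ep in c("os", "pfs")) {
      cv <- config$curves[[a]][[ep]]
      nm <- paste0("curves/", a, "/", ep)
      if (is.null(cv)) { errs <- c(errs, paste0(nm, ": missing")); next }
      ok <- try(surv_curve(cv$family, cv$scale, cv$shape), silent = TRUE)
      if (inherits(ok, "try-error"))
        errs <- c(errs, paste0(nm, ": ", attr(ok, "condition")$message))
    }
    arm <- config$arms[[a]]
    if (is.null(arm)) { errs <- c(errs, paste0("arms/", a, ": missing")); next }
    errs <- check_pv(arm$post_discontinuation_rate,
                     paste0("arms/", a, "/post_discontinuation_rate"), 1, errs)
    errs <- check_pv(arm$ae_disutility, paste0("arms/", a, "/ae_disutility"), 1, errs)
    for (ae in names(arm$ae_risks))
      errs <- check_pv(arm$ae_risks[[ae]], paste0("arms/", a, "/ae_risks/", ae), 1, errs)
    missing_cost <- setdiff(names(arm$ae_risks), names(config$costs$ae))
    if (length(missing_cost))
      errs <- c(errs, paste0("costs/ae: no unit cost for ",
                             paste(missing_cost, collapse = ", ")))
    bad_drug <- setdiff(arm$drugs, names(config$costs$drugs))
    if (length(bad_drug))
      errs <- c(errs, paste0("arms/", a, "/drugs: no cost entry for ",
                             paste(bad_drug, collapse = ", ")))
  }
  for (u in names(config$utilities))
    errs <- check_pv(config$utilities[[u]], paste0("utilities/", u), 1, errs)
  for (d in names(config$costs$drugs))
    errs <- check_pv(config$costs$drugs[[d]], paste0("costs/drugs/", d), Inf, errs)
  for (d in names(config$costs$ae))
    errs <- check_pv(config$costs$ae[[d]], paste0("costs/ae/", d), Inf, errs)
  for (d in names(config$costs$routine))
    errs <- check_pv(config$costs$routine[[d]], paste0("costs/routine/", d), Inf, errs)
  errs <- check_pv(config$costs$best_supportive_care, "costs/best_supportive_care", Inf, errs)
  errs <- check_pv(config$costs$terminal_care, "costs/terminal_care", Inf, errs)
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(config)
}

# ---- parameter table & path access ----------------------------------------

#' Table of uncertain parameters
#'
#' Flattens every scalar input that carries a (low, high) range into one row:
#' the sampling frame for one-way and probabilistic sensitivity analysis.
#' Parameters shared between arms (utilities, adverse-event unit costs, drug
#' and routine costs, the discount rate) appear once and are therefore varied
#' or sampled jointly for both arms.
#'
#' @param config An `npccea_config`.
#' @return A data frame with columns `parameter` (a `/`-separated path into
#'   the configuration), `base`, `low`, `high`, `dist`.
#' @export
parameter_table <- function(config) {
  rows <- list()
  add <- function(path, x) rows[[length(rows) + 1L]] <<-
    data.frame(parameter = path, base = x$base, low = x$low, high = x$high,
               dist = x$dist, stringsAsFactors = FALSE)
  add("model/discount_rate", config$model$discount_rate)
  for (u in names(config$utilities))
    add(paste0("utilities/", u), config$utilities[[u]])
  for (a in names(config$arms)) {
    arm <- config$arms[[a]]
    add(paste0("arms/", a, "/post_discontinuation_rate"),
        arm$post_discontinuation_rate)
    add(paste0("arms/", a, "/ae_disutility"), arm$ae_disutility)
    for (ae in names(arm$ae_risks))
      add(paste0("arms/", a, "/ae_risks/", ae), arm$ae_risks[[ae]])
  }
  for (d in names(config$costs$drugs))
    add(paste0("costs/drugs/", d), config$costs$drugs[[d]])
  for (d in names(config$costs$ae))
    add(paste0("costs/ae/", d), config$costs$ae[[d]])
  for (d in names(config$costs$routine))
    add(paste0("costs/routine/", d), config$costs$routine[[d]])
  add("costs/best_supportive_care", config$costs$best_supportive_care)
  add("costs/terminal_care", config$costs$terminal_care)
  do.call(rbind, rows)
}

#' Set one configuration value by path
#'
#' @param config An `npccea_config`.
#' @param path `/`-separated path as in [parameter_table()]`$parameter`.
#' @param value New base value.
#' @return The modified configuration (ranges are left untouched; validation
#'   of range ordering is relaxed for the perturbed entry).
#' @export
config_set <- function(config, path, value) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    if (is.null(node[[k]])) stop("unknown parameter path: ", path)
    node <- node[[k]]
  }
  set_rec <- function(x, keys, value) {
    if (length(keys) == 0) { x$base <- value; return(x) }
    x[[keys[1]]] <- set_rec(x[[keys[1]]], keys[-1], value)
    x
  }
  set_rec(config, keys, value)
}

#' Get one configuration base value by path
#' @inheritParams config_set
#' @return The base value stored at `path`.
#' @export
config_get <- function(config, path) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    if (is.null(node[[k]])) stop("unknown parameter path: ", path)
    node <- node[[k]]
  }
  node$base
}
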