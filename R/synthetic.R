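#' Simulate censored pseudo individual-patient data
#'
#' Draws event times from a parametric survival curve by inverse-CDF
#' sampling and applies administrative right-censoring: each patient's
#' follow-up ends at `censor_time` minus a uniform accrual offset in
#' `[0, accrual_window]`, emulating staggered enrolment with a common
#' data cut-off. This is the synthetic stand-in for reconstructing patient
#' times from published Kaplan-Meier curves, so the fitting stage can be
#' exercised without any trial data.
#'
#' @param curve A [surv_curve()].
#' @param n Number of patients (default 263, one trial arm).
#' @param censor_time Administrative censoring time in months
#'   (default 24); `NULL` disables censoring so every event is observed.
#' @param accrual_window Width of the uniform accrual offset in months.
#' @param seed Optional integer seed for exact reproducibility.
#' @return A data frame with columns `time_months` and `event` (1 = event
#'   observed, 0 = censored).
#' @export
simulate_ipd <- function(curve, n = 263, censor_time = 24,
                         accrual_window = 0, seed = NULL) {
  stopifnot(inherits(curve, c("surv_curve", "surv_curve_ph")), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n)
  t_event <- invert_survival(curve, u)
  if (is.null(censor_time)) {
    return(data.frame(time_months = t_event, event = 1L))
  }
  stopifnot(censor_time > 0, accrual_window >= 0, accrual_window < censor_time)
  c_i <- censor_time - runif(n, 0, accrual_window)
  event <- as.integer(t_event <= c_i)
  data.frame(time_months = pmin(t_event, c_i), event = event)
}

# inverse of S: time at which survival equals u
invert_survival <- function(curve, u) {
  if (inherits(curve, "surv_curve_ph"))
    return(invert_survival(curve$baseline, u^(1 / curve$hr)))
  lam <- curve$scale; gam <- curve$shape
  switch(curve$family,
    exponential = -log(u) / lam,
    weibull     = (-log(u) / lam)^(1 / gam),
    loglogistic = ((1 - u) / u)^(1 / gam) / lam,
    gompertz    = log1p(-(gam / lam) * log(u)) / gam,
    lognormal   = stats::qlnorm(u, lam, gam, lower.tail = FALSE))
}

#' Kaplan-Meier estimator
#'
#' Product-limit estimate of the survival function of a censored sample,
#' with Greenwood standard errors (computed via the survival package).
#'
#' @param data Data frame with columns `time_months`, `event`.
#' @return A data frame with one row per distinct event/censoring time:
#'   `time`, `survival`, `n_risk`, `n_event`, `n_censor`, `std_err`
#'   (Greenwood standard error of the survival estimate).
#' @export
km_estimator <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("time_months", "event") %in% names(data)))
  if (sum(data$event) < 1) stop("need at least one observed event")
  sf <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = data)
  data.frame(time = sf$time, survival = sf$surv, n_risk = sf$n.risk,
             n_event = sf$n.event, n_censor = sf$n.censor,
             std_err = sf$std.err * sf$surv)
}

#' Emulate graph-digitizer output from a Kaplan-Meier curve
#'
#' Samples a Kaplan-Meier step function on a regular time grid and adds
#' truncated Gaussian jitter, mimicking the coordinate imprecision of
#' manual curve digitization. The output is clamped to `[0, 1]` and
#' re-monotonized (running minimum), and starts at `(0, 1)`.
#'
#' @param km A data frame from [km_estimator()] (columns `time`,
#'   `survival`).
#' @param m Number of grid points (>= 2), spanning 0 to the last KM time.
#' @param jitter_sd Standard deviation of the additive noise (0 = exact
#'   curve values).
#' @param seed Optional integer seed.
#' @return A data frame with columns `time_months`, `survival`.
#' @export
digitize_emulate <- function(km, m = 40, jitter_sd = 0, seed = NULL) {
  stopifnot(m >= 2, jitter_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  step <- stats::stepfun(km$time, c(1, km$survival), right = FALSE)
  grid <- seq(0, max(km$time), length.out = m)
  s <- step(grid)
  if (jitter_sd > 0) s <- s + stats::rnorm(m, 0, jitter_sd)
  s <- pmin(pmax(s, 0), 1)
  s[1] <- 1
  s <- cummin(s)
  data.frame(time_months = grid, survival = s)
}

#' Reconstruct pseudo individual-patient data from digitized coordinates
#'
#' Simplified interval-allocation variant of the Guyot reconstruction: the
#' number alive at each coordinate is `round(n_total * S_j)`; the drop in
#' that count over an interval is allocated as events at the interval's
#' midpoint, and patients still alive after the last coordinate are censored at
#' `censor_time` (or the last coordinate time). Published numbers-at-risk
#' tables are not used; with no censoring before the cut-off, the
#' Kaplan-Meier curve of the reconstructed sample passes through the input
#' coordinates to within `1/n_total`.
#'
#' @param coordinates Data frame with columns `time_months`, `survival`,
#'   monotone non-increasing from 1.
#' @param n_total Cohort size to allocate.
#' @param censor_time Censoring time for patients alive at the end
#'   (default: last coordinate time).
#' @return A data frame with columns `time_months`, `event`.
#' @export
reconstruct_ipd <- function(coordinates, n_total,
                            censor_time = max(coordinates$time_months)) {
  stopifnot(is.data.frame(coordinates),
            all(c("time_months", "survival") %in% names(coordinates)),
            n_total >= 1)
  s <- coordinates$survival
  tt <- coordinates$time_months
  if (is.unsorted(tt)) stop("coordinates must be ordered by time")
  if (any(diff(s) > 1e-12)) stop("survival coordinates must be non-increasing")
  if (abs(s[1] - 1) > 1e-9) stop("survival must start at 1")
  alive <- round(n_total * s)
  events <- -diff(alive)
  times <- (tt[-1] + tt[-length(tt)]) / 2
  out <- data.frame(
    time_months = c(rep(times, events),
                    rep(censor_time, alive[length(alive)])),
    event = c(rep(1L, sum(events)), rep(0L, alive[length(alive)])))
  out[order(out$time_months, -out$event), , drop = FALSE]
}

#' Write pseudo individual-patient data as CSV
#'
#' @param ipd Data frame with columns `time_months`, `event`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(ipd[, c("time_months", "event")], path, row.names = FALSE)
  invisible(path)
}

#' Read pseudo individual-patient data from CSV
#'
#' @param path CSV file with header `time_months,event`.
#' @return A data frame with columns `time_months`, `event`.
#' @export
read_ipd <- function(path) {
  ipd <- utils::read.csv(path)
  if (!all(c("time_months", "event") %in% names(ipd)))
    stop("IPD file must have columns time_months,event: ", path)
  ipd
}
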